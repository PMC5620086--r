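#' Assemble the genotype-transcript-phenotype network
#'
#' Builds the integrated network from association records across the four
#' mapping layers. Nodes are typed (snp, transcript, phenotype,
#' epistasis_junction); edges are directed predictor -> target and carry the
#' layer, effect value, sign class, sex pattern, significance tier and a
#' width proportional to |effect| scaled to \[0.5, 5\]. An epistatic pair is
#' rendered as a junction node with two incoming source edges and one
#' outgoing effect-carrying edge (the "Y" shape), so the junction always has
#' degree 3. Node ordering is deterministic (type, then id), so rebuilding
#' from shuffled records yields an identical network.
#'
#' @param records association record data.frame (e.g. a `study_result`'s
#'   `combined` table or any [map_layer()] records).
#' @param trait phenotype node id (default "startle").
#' @return An object of class `genetic_network` with `nodes` and `edges`
#'   data.frames.
#' @export
build_network <- function(records, trait = "startle") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("layer", "source", "source2", "target", "effect",
            "effect_female", "effect_male", "tier")
  if (nrow(records) && !all(need %in% names(records))) {
    stopf("records need columns %s", paste(need, collapse = ", "))
  }
  if (!nrow(records)) {
    records <- empty_records()
  }
  if (!all(records$layer %in% layer_levels)) {
    stopf("unknown layer label: %s",
          records$layer[!(records$layer %in% layer_levels)][1L])
  }
  # layer type discipline: no SNP targets except via t-layers onto transcripts
  src_kind <- ifelse(records$layer %in% c("QTS", "tQTS"), "snp", "transcript")
  tgt_kind <- ifelse(records$layer %in% c("QTS", "QTT"), "phenotype", "transcript")
  records$target[tgt_kind == "phenotype"] <- trait

  dup_key <- paste(records$layer, records$source, records$source2,
                   records$target, sep = "\r")
  if (anyDuplicated(dup_key)) {
    d <- records[dup_key %in% dup_key[duplicated(dup_key)], , drop = FALSE]
    agree <- all(tapply(d$effect, paste(d$layer, d$source, d$source2, d$target),
                        function(e) length(unique(e)) == 1L))
    if (!agree) {
      stopf("conflicting duplicate records for %s %s -> %s",
            d$layer[1L], d$source[1L], d$target[1L])
    }
    records <- records[!duplicated(dup_key), , drop = FALSE]
  }

  nodes <- data.frame(id = trait, type = "phenotype", label = trait,
                      stringsAsFactors = FALSE)
  add_node <- function(id, type) {
    new <- !(id %in% nodes$id)
    if (any(new)) {
      nodes <<- rbind(nodes, data.frame(id = id[new], type = type[new],
                                        label = id[new],
                                        stringsAsFactors = FALSE))
    }
  }
  edges <- data.frame(
    source = character(), target = character(), layer = character(),
    effect = numeric(), sign_class = character(), sex_pattern = character(),
    tier = character(), width = numeric(), role = character(),
    stringsAsFactors = FALSE
  )
  add_edge <- function(source, target, layer, effect, ef, em, tier, role) {
    edges[nrow(edges) + 1L, ] <<- list(
      source, target, layer, effect,
      if (is.na(effect) || effect == 0) NA_character_
      else if (effect > 0) "positive" else "negative",
      sex_pattern_of(ef, em), tier, NA_real_, role
    )
  }

  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    add_node(rec$target, tgt_kind[r])
    if (is.na(rec$source2)) {
      add_node(rec$source, src_kind[r])
      add_edge(rec$source, rec$target, rec$layer, rec$effect,
               rec$effect_female, rec$effect_male, rec$tier, "direct")
    } else {
      jid <- paste("epi", rec$source, rec$source2, sep = "|")
      add_node(c(rec$source, rec$source2), rep(src_kind[r], 2L))
      add_node(jid, "epistasis_junction")
      add_edge(rec$source, jid, rec$layer, NA_real_, NA_real_, NA_real_,
               rec$tier, "epistasis_source")
      add_edge(rec$source2, jid, rec$layer, NA_real_, NA_real_, NA_real_,
               rec$tier, "epistasis_source")
      add_edge(jid, rec$target, rec$layer, rec$effect,
               rec$effect_female, rec$effect_male, rec$tier, "epistasis_target")
    }
  }

  # width proportional to |effect| mapped onto [0.5, 5]
  ae <- abs(edges$effect)
  if (any(!is.na(ae))) {
    lo <- min(ae, na.rm = TRUE); hi <- max(ae, na.rm = TRUE)
    edges$width <- if (hi > lo) 0.5 + 4.5 * (ae - lo) / (hi - lo) else 2.75
    edges$width[is.na(ae)] <- NA_real_
  }

  type_order <- c(snp = 1L, transcript = 2L, phenotype = 3L,
                  epistasis_junction = 4L)
  nodes <- nodes[order(type_order[nodes$type], nodes$id, method = "radix"), ,
                 drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(match(edges$layer, layer_levels), edges$source,
                       edges$target, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, trait = trait),
            class = "genetic_network")
}

# Sign pattern across sexes; matches the figure-legend semantics
# (both-positive, both-negative, female-positive/male-negative "yellow",
# male-positive/female-negative "orange").
sex_pattern_of <- function(ef, em) {
  if (is.na(ef) || is.na(em)) return(NA_character_)
  if (ef >= 0 && em >= 0) return("both_same_sign_positive")
  if (ef <= 0 && em <= 0) return("both_same_sign_negative")
  if (ef > 0 && em < 0) return("female_pos_male_neg")
  "male_pos_female_neg"
}

#' @export
print.genetic_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "genetic_network '%s': %d nodes (%d snp, %d transcript, %d junction), %d edges (%d direct, %d indirect)\n",
    x$trait, nrow(x$nodes), s$nodes_by_type[["snp"]],
    s$nodes_by_type[["transcript"]], s$epistasis_junctions,
    nrow(x$edges), s$direct_edges, s$indirect_edges
  ))
  invisible(x)
}

#' Summarize a genetic network
#'
#' Counts nodes by type and edges by layer, and classifies effect-carrying
#' edges as direct (targeting the phenotype node) or indirect (targeting a
#' transcript).
#'
#' @param net a `genetic_network`.
#' @return list of counts.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "genetic_network"))
  types <- c("snp", "transcript", "phenotype", "epistasis_junction")
  nbt <- vapply(types, function(t) sum(net$nodes$type == t), integer(1L))
  ebl <- vapply(layer_levels, function(l) sum(net$edges$layer == l), integer(1L))
  eff <- net$edges[net$edges$role %in% c("direct", "epistasis_target"), ,
                   drop = FALSE]
  tgt_type <- net$nodes$type[match(eff$target, net$nodes$id)]
  list(
    nodes = nrow(net$nodes),
    nodes_by_type = nbt,
    edges = nrow(net$edges),
    edges_by_layer = ebl,
    epistasis_junctions = nbt[["epistasis_junction"]],
    direct_edges = sum(tgt_type == "phenotype"),
    indirect_edges = sum(tgt_type == "transcript")
  )
}

#' Export / import a genetic network
#'
#' GraphML (via igraph) carries all node and edge attributes; SIF carries
#' topology with the layer as the interaction type; JSON is a lossless
#' node-link document. Exports are deterministic: two exports of the same
#' network are byte-identical.
#'
#' @param net a `genetic_network`.
#' @param path output file.
#' @param format "graphml", "sif" or "json".
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "json")) {
  stopifnot(inherits(net, "genetic_network"))
  if (length(format) == 1L && !format %in% c("graphml", "sif", "json")) {
    stopf("unsupported network format: %s", format)
  }
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    writeLines(paste(net$edges$source, net$edges$layer, net$edges$target,
                     sep = "\t"), path)
  } else {
    obj <- list(
      trait = net$trait,
      nodes = net$nodes,
      edges = net$edges
    )
    jsonlite::write_json(obj, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(
      id = igraph::vertex_attr(g, "name"),
      type = igraph::vertex_attr(g, "type"),
      label = igraph::vertex_attr(g, "label"),
      stringsAsFactors = FALSE
    )
    el <- igraph::as_edgelist(g)
    num_or_na <- function(x) {
      x[!is.finite(x)] <- NA_real_
      x
    }
    chr_or_na <- function(x) {
      x[x == ""] <- NA_character_
      x
    }
    edges <- data.frame(
      source = el[, 1L], target = el[, 2L],
      layer = igraph::edge_attr(g, "layer"),
      effect = num_or_na(igraph::edge_attr(g, "effect")),
      sign_class = chr_or_na(igraph::edge_attr(g, "sign_class")),
      sex_pattern = chr_or_na(igraph::edge_attr(g, "sex_pattern")),
      tier = igraph::edge_attr(g, "tier"),
      width = num_or_na(igraph::edge_attr(g, "width")),
      role = igraph::edge_attr(g, "role"),
      stringsAsFactors = FALSE
    )
    trait <- nodes$id[nodes$type == "phenotype"][1L]
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
    edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
    if (!"effect" %in% names(edges)) edges$effect <- NA_real_
    trait <- obj$trait
  }
  type_order <- c(snp = 1L, transcript = 2L, phenotype = 3L,
                  epistasis_junction = 4L)
  nodes <- nodes[order(type_order[nodes$type], nodes$id, method = "radix"), ,
                 drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(match(edges$layer, layer_levels), edges$source,
                       edges$target, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, trait = trait),
            class = "genetic_network")
}

# igraph view of the network, with NA attributes encoded for GraphML
# round-tripping (NaN for numerics, "" for strings).
as_igraph <- function(net) {
  edges <- net$edges
  edges$effect[is.na(edges$effect)] <- NaN
  edges$width[is.na(edges$width)] <- NaN
  edges$sign_class[is.na(edges$sign_class)] <- ""
  edges$sex_pattern[is.na(edges$sex_pattern)] <- ""
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = net$nodes)
}

#' @export
plot.genetic_network <- function(x, ...) {
  g <- as_igraph(x)
  shapes <- c(snp = "circle", transcript = "square", phenotype = "rectangle",
              epistasis_junction = "none")
  cols <- c(snp = "indianred2", transcript = "palegreen3",
            phenotype = "gold", epistasis_junction = "grey40")
  tp <- igraph::vertex_attr(g, "type")
  w <- igraph::edge_attr(g, "width")
  w[!is.finite(w)] <- 0.5
  igraph::plot.igraph(
    g,
    vertex.color = cols[tp],
    vertex.size = ifelse(tp == "epistasis_junction", 2, 12),
    vertex.label.cex = 0.7,
    edge.width = w,
    edge.arrow.size = 0.3,
    ...
  )
  invisible(x)
}
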