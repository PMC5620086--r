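# Internal helpers shared across modules.

# Population (divide-by-n) variance; the component/heritability convention
# throughout the package, so that noise-free total heritability is exactly 1.
popvar <- function(x) {
  x <- as.numeric(x)
  mean((x - mean(x))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical key for an unordered locus pair, used in truth maps, term names
# and network junction ids. Ids themselves never contain ":".
pair_key <- function(i, j) paste(i, j, sep = ":")

split_pair_key <- function(key) strsplit(key, ":", fixed = TRUE)

# Observation layout for line x sex modelling: all lines as females first,
# then the same lines as males. Keeping both sex slices of a line at a fixed
# offset makes joint (line-level) permutation trivial.
obs_frame <- function(line_ids) {
  data.frame(
    line = rep(line_ids, 2L),
    sex = rep(c("female", "male"), each = length(line_ids)),
    stringsAsFactors = FALSE
  )
}

# Sex contrast: +1 female, -1 male (sum-to-zero coding).
sex_contrast <- function(n_lines) rep(c(1, -1), each = n_lines)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}
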