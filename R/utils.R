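#' @importFrom rlang .data
#' @importFrom stats rexp runif setNames
#' @importFrom utils head tail
NULL

# Deterministic per-patient substream seed: a fixed affine mix of the global
# seed and the patient counter, so patient i's stream is unchanged when
# n_patients changes.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 65521 * 1103515245 +
                as.double(i) * 12345 + 982451653) %% 2147483647)
}

days_between <- function(from, to) as.integer(as.Date(to) - as.Date(from))

# sample() misbehaves when x has length 1; this always treats x as a set.
sample_one <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

join_codes <- function(...) paste(c(...), collapse = "|")

split_classes <- function(x) strsplit(x, "+", fixed = TRUE)

# locale-independent (C collation) sort for class-set keys
sort_c <- function(x) sort(x, method = "radix")
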