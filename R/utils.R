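# internal numerical helpers

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
gamma_key <- function(gamma) {
  paste(which(gamma != 0L), collapse = ",")
}

# integer seed derived from a base seed and a stream label, kept < 2^31
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 69069 + offs) %% 2147483647)
}
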