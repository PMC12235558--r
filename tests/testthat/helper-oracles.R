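# exhaustive-permutation oracle for maximum-weight matching (<= 7x7)
brute_force_match <- function(w) {
  nA <- nrow(w); nB <- ncol(w)
  if (nA > nB) return(brute_force_match(t(w)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(nB))) {
    tw <- sum(w[cbind(seq_len(nA), p[seq_len(nA)])])
    if (tw > best) best <- tw
  }
  best
}
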