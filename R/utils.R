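# internal helpers

# k1-range carrying all but < 1e-22 of the Binomial(k, 1/2) mass
binom_support <- function(k) {
  if (k <= 64) return(0:k)
  hw <- ceiling(5 * sqrt(k))
  max(0L, floor(k / 2 - hw)):min(k, ceiling(k / 2 + hw))
}

# aggregate ordered (k, kp, p) triples, summing duplicate pairs
aggregate_pairs <- function(k, kp, p) {
  key <- paste(format(k, scientific = FALSE, trim = TRUE),
               format(kp, scientific = FALSE, trim = TRUE))
  s <- rowsum(p, key)
  parts <- do.call(rbind, strsplit(rownames(s), " ", fixed = TRUE))
  out <- data.frame(k = as.numeric(parts[, 1]), kp = as.numeric(parts[, 2]),
                    p = as.vector(s))
  out[order(out$k, out$kp), , drop = FALSE]
}

# decimal plus exact-fraction rendering for report output
format_fraction <- function(x) {
  if (!is.finite(x)) return(as.character(x))
  fr <- as.character(MASS::fractions(x, max.denominator = 1e6))
  if (identical(fr, format(x))) fr else paste0(fr, " (", signif(x, 8), ")")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
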