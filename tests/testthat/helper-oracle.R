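# Independent brute-force oracle: evaluates the within-class entropy sum by
# direct normalization of each sub-histogram (no prefix tables, no shared
# code with the package internals) and scans all threshold vectors in
# lexicographic order.  Same documented tie rule as the package: values
# within 1e-10 of the maximum tie, smallest vector wins.

brute_class_entropy <- function(q, lo, hi, base = 2) {
  # class covers 0-based levels lo .. hi-1
  sub <- q[(lo + 1):hi]
  e <- sum(sub)
  if (e == 0) return(NA_real_)
  p <- sub / e
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

brute_objective <- function(q, cuts, base = 2) {
  Z <- length(q)
  bounds <- c(0L, cuts, Z)
  total <- 0
  for (i in seq_len(length(cuts) + 1L)) {
    h <- brute_class_entropy(q, bounds[i], bounds[i + 1L], base = base)
    if (is.na(h)) return(NA_real_)
    total <- total + h
  }
  total
}

all_cut_vectors <- function(Z, m) {
  if (m == 1L) matrix(seq_len(Z - 1L), nrow = 1L) else utils::combn(seq_len(Z - 1L), m)
}

brute_search <- function(q, m, base = 2) {
  cuts <- all_cut_vectors(length(q), m)
  vals <- apply(cuts, 2, function(u) brute_objective(q, u, base = base))
  if (all(is.na(vals))) stop("no feasible vector")
  best <- which(vals >= max(vals, na.rm = TRUE) - 1e-10)[1]
  list(cuts = cuts[, best], value = vals[best])
}

# Random normalized histograms with occasional empty levels.
random_hist <- function(Z, zero_frac = 0.3) {
  w <- stats::rgamma(Z, shape = 0.6)
  w[stats::runif(Z) < zero_frac] <- 0
  if (sum(w > 0) < 3) w[sample.int(Z, 3)] <- 1
  gray_histogram(w / sum(w))
}

random_image <- function(nr, nc, Z) {
  gray_image(matrix(sample.int(Z, nr * nc, replace = TRUE) - 1L, nr, nc),
             n_levels = Z)
}
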