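# Independent oracles, deliberately naive: a plain-R three-matrix affine DP
# for glocal scores, and a per-base brute-force genotype likelihood
# evaluator. These share no code with the implementations they check.

oracle_glocal_score <- function(read, ref, match = 1, mismatch = 5,
                                gap_open = 2, gap_extend = 1) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(f)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  D <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0                              # free reference prefix
  for (i in 2:(n + 1)) {
    for (j in 1:(m + 1)) {
      if (j > 1) {
        s <- if (r[i - 1] == f[j - 1]) match else -mismatch
        M[i, j] <- max(M[i - 1, j - 1], I[i - 1, j - 1], D[i - 1, j - 1]) + s
      }
      I[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     I[i - 1, j] - gap_extend,
                     D[i - 1, j] - gap_open - gap_extend)
      if (j > 1) {
        D[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                       I[i, j - 1] - gap_open - gap_extend,
                       D[i, j - 1] - gap_extend)
      }
    }
  }
  max(M[n + 1, ], I[n + 1, ])              # trailing deletions are free
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

oracle_genotype_ll <- function(bases, quals, ref, alt) {
  ll <- c(hom_ref = 0, het = 0, hom_alt = 0)
  for (k in seq_along(bases)) {
    e <- 10^(-quals[k] / 10)
    p_base <- function(a) if (bases[k] == a) 1 - e else e / 3
    ll["hom_ref"] <- ll["hom_ref"] + log(0.5 * p_base(ref) + 0.5 * p_base(ref))
    ll["het"] <- ll["het"] + log(0.5 * p_base(ref) + 0.5 * p_base(alt))
    ll["hom_alt"] <- ll["hom_alt"] + log(0.5 * p_base(alt) + 0.5 * p_base(alt))
  }
  ll
}

# Verify that a truth event string rebuilds the read from its haplotype:
# M emits the reference base, X a different base, I any base, D consumes the
# reference silently. Returns TRUE or a description of the first violation.
check_event_reconstruction <- function(events, aligned_seq, ref_seq, start) {
  ev <- strsplit(events, "")[[1]]
  rc <- strsplit(aligned_seq, "")[[1]]
  fc <- strsplit(ref_seq, "")[[1]]
  i <- 1L; j <- start
  for (op in ev) {
    if (op == "M") {
      if (rc[i] != fc[j]) return(sprintf("M mismatch at read %d", i))
      i <- i + 1L; j <- j + 1L
    } else if (op == "X") {
      if (rc[i] == fc[j]) return(sprintf("X matches at read %d", i))
      i <- i + 1L; j <- j + 1L
    } else if (op == "I") {
      i <- i + 1L
    } else if (op == "D") {
      j <- j + 1L
    } else {
      return(paste("unknown op", op))
    }
  }
  if (i != length(rc) + 1L) return("read not fully consumed")
  TRUE
}
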