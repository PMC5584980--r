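# Shared fixtures, built in code at test time.

# a deterministic PWM with all mass concentrated at `hot` residues
one_hot_pwm <- function(L, hot = rep("A", L)) {
  m <- matrix(0, nrow = L, ncol = 20,
              dimnames = list(NULL, aa_alphabet()))
  for (i in seq_len(L)) m[i, hot[i]] <- 1
  pwm(m)
}

# anchored PWM used widely in the deconvolution tests: anchor residues at
# P2 and PL with probability `p`, remaining mass uniform over the other 19
anchored_pwm <- function(L, r2, rL, p = 0.9) {
  m <- matrix(1 / 20, nrow = L, ncol = 20,
              dimnames = list(NULL, aa_alphabet()))
  for (spec in list(c(2L, r2), c(L, rL))) {
    i <- as.integer(spec[1])
    row <- rep((1 - p) / 19, 20)
    row[match(spec[2], aa_alphabet())] <- p
    m[i, ] <- row
  }
  pwm(m)
}

# random valid PWM (rows from a Dirichlet)
random_pwm <- function(L, alpha = 1) {
  m <- matrix(rgamma(L * 20, alpha), nrow = L)
  pwm(m / rowSums(m))
}

# write a character vector as a temp peptide file
write_peps <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# tiny in-memory catalog from explicit PWMs: motifs[[sample]] = list of pwms
toy_catalog <- function(pwms_by_sample, genotypes, n = 100L) {
  motifs <- lapply(names(pwms_by_sample), function(s) {
    lapply(seq_along(pwms_by_sample[[s]]), function(k) {
      list(index = k, pwm = pwms_by_sample[[s]][[k]],
           peptides = paste0("PEP", s, k, seq_len(3)), n = n)
    })
  })
  names(motifs) <- names(pwms_by_sample)
  motif_catalog(motifs, genotypes, length = nrow(pwms_by_sample[[1]][[1]]))
}
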