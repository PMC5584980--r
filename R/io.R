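#' Read a peptide list file
#'
#' Plain text, one peptide per line, no header. Peptides are uppercased,
#' tokens containing non-canonical characters (X, U, B, Z, `*`, ...) are
#' dropped, lengths outside `[min_len, max_len]` are dropped, and the
#' survivors are deduplicated within each length. Counts of read, dropped
#' and deduplicated tokens are reported via [message()].
#'
#' @param path Path to the peptide list.
#' @param min_len,max_len Inclusive length bounds at ingestion (default
#'   8--14; only 9- and 10-mers are deconvoluted downstream).
#' @return Named list: length (as character) -> character vector of unique
#'   peptides.
#' @export
read_peptide_list <- function(path, min_len = 8L, max_len = 14L) {
  if (!file.exists(path)) stop("cannot read peptide list: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  n_read <- length(raw)
  pep <- toupper(raw)
  ok <- is_canonical_peptide(pep)
  n_noncanon <- sum(!ok)
  pep <- pep[ok]
  len <- nchar(pep)
  in_range <- len >= min_len & len <= max_len
  n_len <- sum(!in_range)
  pep <- pep[in_range]
  len <- len[in_range]
  out <- lapply(split(pep, len), unique)
  n_dedup <- length(pep) - sum(lengths(out))
  message(sprintf(
    "%s: read %d peptides; dropped %d non-canonical, %d out-of-length; %d duplicates removed; %d kept",
    basename(path), n_read, n_noncanon, n_len, n_dedup, sum(lengths(out))))
  if (n_read == 0L) stop("empty peptide list: ", path)
  out
}

#' Read a sample manifest
#'
#' Tab-separated with header `sample_id<TAB>peptide_file<TAB>alleles`
#' (alleles comma-separated, any accepted dialect). Each row yields one
#' sample dataset: the genotype is validated (1--6 alleles, at most two
#' per locus) and the peptide file is read with [read_peptide_list()].
#' Relative peptide-file paths are resolved against the manifest's
#' directory.
#'
#' @param path Path to the manifest TSV.
#' @param min_len,max_len Passed to [read_peptide_list()].
#' @return List of sample datasets; each is a list with `sample_id`,
#'   `genotype` (compact allele names) and `peptides_by_length`.
#' @export
read_manifest <- function(path, min_len = 8L, max_len = 14L) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "peptide_file", "alleles")
  if (!all(need %in% names(tab))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    alleles <- strsplit(tab$alleles[i], ",", fixed = TRUE)[[1]]
    genotype <- validate_genotype(alleles, sample_id = tab$sample_id[i])
    pf <- tab$peptide_file[i]
    if (!file.exists(pf)) pf <- file.path(dirname(path), pf)
    sample_dataset(tab$sample_id[i], genotype,
                   read_peptide_list(pf, min_len, max_len))
  })
  names(out) <- tab$sample_id
  out
}

#' Construct a sample dataset
#'
#' @param sample_id Sample identifier.
#' @param genotype Character vector of alleles (validated).
#' @param peptides_by_length Named list: length -> unique peptides.
#' @return A list of class `sample_dataset`.
#' @export
sample_dataset <- function(sample_id, genotype, peptides_by_length) {
  genotype <- validate_genotype(genotype, sample_id)
  peptides_by_length <- lapply(peptides_by_length, unique)
  structure(list(sample_id = sample_id, genotype = genotype,
                 peptides_by_length = peptides_by_length),
            class = "sample_dataset")
}

#' @export
print.sample_dataset <- function(x, ...) {
  cat("Sample", x$sample_id, "-", paste(format_allele(x$genotype), collapse = " "),
      "\n  peptides:",
      paste(sprintf("%s-mers: %d", names(x$peptides_by_length),
                    lengths(x$peptides_by_length)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a proteome FASTA
#'
#' Sequences are uppercased; record ids are the first whitespace-delimited
#' token of the header. Duplicate ids are an error.
#'
#' @param path FASTA path.
#' @return Named character vector: protein id -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  if (anyDuplicated(ids)) {
    stop("duplicate protein id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aas))
  names(seqs) <- ids
  seqs
}

#' Write a named set of protein sequences as FASTA
#'
#' @param proteome Named character vector (id -> sequence).
#' @param path Output path.
#' @export
write_fasta <- function(proteome, path) {
  x <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Sample decoy peptides from a proteome
#'
#' Draws `n` length-`L` windows uniformly with replacement over all valid
#' windows of all proteins (windows containing non-canonical residues are
#' excluded). Deterministic for a fixed seed. This is the construction
#' used for the 100,000-peptide empirical score background and for
#' 99-fold decoy sets in benchmarking.
#'
#' @param proteome Named character vector (id -> sequence).
#' @param L Window (peptide) length.
#' @param n Number of peptides to draw.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return Character vector of `n` peptides.
#' @export
sample_random_peptides <- function(proteome, L, n, seed = NULL) {
  stopifnot(L >= 1, n >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  seqs <- proteome[nchar(proteome) >= L]
  windows <- unlist(lapply(seqs, function(s) {
    starts <- seq_len(nchar(s) - L + 1L)
    substring(s, starts, starts + L - 1L)
  }), use.names = FALSE)
  windows <- windows[is_canonical_peptide(windows)]
  if (length(windows) == 0L) {
    stop("proteome contains no valid window of length ", L)
  }
  windows[sample.int(length(windows), n, replace = TRUE)]
}

#' Write / read a PWM file
#'
#' Tab-separated text: a first line
#' `#PWM length=<L> alphabet=ACDEFGHIKLMNPQRSTVWY`, then 20 rows (one per
#' residue in alphabetical order) of `L` probability columns P1..PL.
#' Round-trips reproduce the matrix to within 1e-12 per entry.
#'
#' @param p A [pwm()].
#' @param path File path.
#' @return `read_pwm` returns a [pwm()]; `write_pwm` returns `path`
#'   invisibly.
#' @export
write_pwm <- function(p, path) {
  stopifnot(is_pwm(p))
  L <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#PWM length=%d alphabet=%s", L,
                     paste(aa_alphabet(), collapse = "")), con)
  m <- t(unclass(p))  # residues x positions on disk
  for (a in seq_len(20)) {
    writeLines(paste(c(aa_alphabet()[a], format(m[a, ], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  if (!file.exists(path)) stop("cannot read PWM file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L || !grepl("^#PWM length=\\d+", lines[1])) {
    stop("malformed PWM file (missing header): ", path)
  }
  L <- as.integer(sub("^#PWM length=(\\d+).*$", "\\1", lines[1]))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != 20L) {
    stop("PWM file must have 20 residue rows, got ", length(body), ": ", path)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  res <- vapply(parts, `[`, character(1), 1)
  if (!identical(sort(res), aa_alphabet())) {
    stop("PWM file residue rows do not cover the 20-letter alphabet: ", path)
  }
  m <- matrix(NA_real_, nrow = 20, ncol = L, dimnames = list(res, NULL))
  for (a in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[a]][-1]))
    if (length(v) != L || anyNA(v)) stop("bad probability row for residue ",
                                         res[a], " in ", path)
    m[a, ] <- v
  }
  m <- m[aa_alphabet(), , drop = FALSE]
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6)) {
    stop("PWM file columns not normalized (max deviation ",
         format(max(abs(cs - 1))), "): ", path)
  }
  pwm(t(m / rep(cs, each = 20)))
}

#' Write a sample manifest and peptide lists
#'
#' Serializes a list of sample datasets into a manifest TSV plus one
#' peptide file per sample (all lengths concatenated), the on-disk layout
#' read back by [read_manifest()].
#'
#' @param samples List of [sample_dataset()] objects.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_manifest <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vapply(samples, function(s) {
    pf <- paste0(s$sample_id, ".txt")
    writeLines(unlist(s$peptides_by_length, use.names = FALSE),
               file.path(dir, pf))
    paste(s$sample_id, pf, paste(s$genotype, collapse = ","), sep = "\t")
  }, character(1))
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(c("sample_id\tpeptide_file\talleles", rows), manifest)
  invisible(manifest)
}
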