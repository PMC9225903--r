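#' Construct a haplotype matrix
#'
#' A haplotype matrix holds `n` phased haplotypes (chromosome copies, rows)
#' over `m` biallelic SNP loci (columns). Entries are coded `1` for the
#' major allele, `0` for the minor allele, and `NA` for a missing call.
#'
#' @param entries An `n x m` matrix (or something coercible to one) whose
#'   entries are 0, 1 or `NA`.
#' @param sample_ids Optional character vector of `n` haplotype labels.
#'   Defaults to `h1..hn`.
#' @param locus_ids Optional character vector of `m` locus labels (rsIDs,
#'   positions, ...). Defaults to `snp1..snpm`.
#'
#' @return An object of class `haplotype_matrix`: an integer matrix with
#'   row and column names carrying the sample and locus ids.
#'
#' @examples
#' hm <- haplotype_matrix(rbind(c(0, 1, 1), c(1, 1, NA)))
#' dim(hm)
#' @export
haplotype_matrix <- function(entries, sample_ids = NULL, locus_ids = NULL) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "integer"
  n <- nrow(entries)
  m <- ncol(entries)
  if (n < 2) {
    stop("a haplotype matrix needs at least 2 haplotype rows, got ", n,
         call. = FALSE)
  }
  if (m < 1) {
    stop("a haplotype matrix needs at least 1 locus column", call. = FALSE)
  }
  bad <- !(entries %in% c(0L, 1L, NA))
  if (any(bad)) {
    stop("haplotype entries must be 0, 1 or NA (missing)", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("h", seq_len(n))
  if (is.null(locus_ids)) locus_ids <- paste0("snp", seq_len(m))
  if (length(sample_ids) != n) {
    stop("length(sample_ids) must equal the number of rows", call. = FALSE)
  }
  if (length(locus_ids) != m) {
    stop("length(locus_ids) must equal the number of columns", call. = FALSE)
  }
  dimnames(entries) <- list(as.character(sample_ids), as.character(locus_ids))
  class(entries) <- c("haplotype_matrix", "matrix", "array")
  entries
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d haplotypes x %d loci (%d missing calls)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  show <- unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(10L, ncol(x))),
                     drop = FALSE]
  print(show)
  if (nrow(x) > 6L || ncol(x) > 10L) cat("...\n")
  invisible(x)
}

sample_ids <- function(hm) rownames(hm)
locus_ids <- function(hm) colnames(hm)

# resolve locus references (integer indices or locus_id strings) to indices
resolve_loci <- function(hm, loci) {
  if (is.character(loci)) {
    idx <- match(loci, colnames(hm))
    if (anyNA(idx)) {
      stop("unknown locus id(s): ", paste(loci[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    return(idx)
  }
  idx <- as.integer(loci)
  if (any(idx < 1L | idx > ncol(hm))) {
    stop("locus index out of range 1..", ncol(hm), call. = FALSE)
  }
  idx
}

#' Read a plain-text haplotype matrix
#'
#' One haplotype per line, symbols `0`, `1` and `-` (missing), either
#' contiguous (`0101`) or whitespace-separated (`0 1 0 1`); the dialect is
#' auto-detected per file. Lines starting with `#` are comments and blank
#' lines are skipped.
#'
#' @param path Path to the text file.
#' @return A [haplotype_matrix()].
#' @export
read_hap_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("no haplotype rows in ", path, call. = FALSE)
  ids_from_comment <- function(key) {
    pat <- paste0("^#\\s*", key, ":")
    ln <- grep(pat, raw)
    if (length(ln) == 0L) return(NULL)
    strsplit(trimws(sub(pat, "", raw[ln[1L]])), "[[:space:]]+")[[1L]]
  }
  rows <- vector("list", length(keep))
  width <- NA_integer_
  for (k in seq_along(keep)) {
    line <- trimws(raw[keep[k]])
    if (grepl("[^01[:space:]-]", line)) {
      stop(sprintf("invalid character at line %d of %s (allowed: 0 1 - whitespace)",
                   keep[k], path), call. = FALSE)
    }
    toks <- if (grepl("[[:space:]]", line)) {
      strsplit(line, "[[:space:]]+")[[1]]
    } else {
      strsplit(line, "")[[1]]
    }
    if (any(nchar(toks) != 1L)) {
      stop(sprintf("malformed token at line %d of %s", keep[k], path),
           call. = FALSE)
    }
    if (is.na(width)) {
      width <- length(toks)
    } else if (length(toks) != width) {
      stop(sprintf("ragged row at line %d of %s (expected %d loci, got %d)",
                   keep[k], path, width, length(toks)), call. = FALSE)
    }
    v <- rep(NA_integer_, length(toks))
    v[toks == "0"] <- 0L
    v[toks == "1"] <- 1L
    rows[[k]] <- v
  }
  ent <- do.call(rbind, rows)
  loci <- ids_from_comment("loci")
  samples <- ids_from_comment("samples")
  if (!is.null(loci) && length(loci) != ncol(ent)) {
    stop(sprintf("#loci: header names %d ids but rows have %d loci",
                 length(loci), ncol(ent)), call. = FALSE)
  }
  if (!is.null(samples) && length(samples) != nrow(ent)) {
    stop(sprintf("#samples: header names %d ids but file has %d rows",
                 length(samples), nrow(ent)), call. = FALSE)
  }
  haplotype_matrix(ent, sample_ids = samples, locus_ids = loci)
}

#' Write a haplotype matrix as plain text
#'
#' Emits one contiguous row per haplotype with `-` for missing calls,
#' preceded by `#samples:` / `#loci:` comment headers carrying the ids;
#' [read_hap_matrix()] on the result reproduces entries, sample ids and
#' locus ids exactly (readers of other tools ignore the comments).
#'
#' @param hm A [haplotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hap_matrix <- function(hm, path) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  chars <- matrix(as.character(unclass(hm)), nrow = nrow(hm))
  chars[is.na(chars)] <- "-"
  lines <- c(paste("#samples:", paste(rownames(hm), collapse = " ")),
             paste("#loci:", paste(colnames(hm), collapse = " ")),
             apply(chars, 1, paste0, collapse = ""))
  tryCatch(suppressWarnings(writeLines(lines, path)),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read phased haplotypes from a VCF file
#'
#' Each sample contributes two haplotype rows (left and right allele of the
#' phased GT). Only biallelic sites whose GT is phased (`|`) in every sample
#' are used; multiallelic or unphased sites are skipped with a message. At
#' each kept site alleles are recoded so that the major allele over all
#' haplotypes is `1` and the minor allele `0`; on an exact frequency tie the
#' REF allele is treated as major.
#'
#' @param path Path to a VCF (v4.x) file with phased genotypes.
#' @return A [haplotype_matrix()] with `2 * n_samples` rows, sample ids
#'   `<sample>_1` / `<sample>_2` and locus ids from the VCF ID column (or
#'   `CHROM:POS` where ID is `.`).
#' @export
read_hap_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                        dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L) {
    stop("VCF has no sample genotype columns", call. = FALSE)
  }
  gt <- gt[, -1, drop = FALSE]          # drop FORMAT
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = nrow(fix),
                                   dimnames = list(NULL, colnames(vcf@gt)[-1]))
  # strip any trailing FORMAT subfields, keep the GT token
  gt[] <- sub(":.*$", "", gt)
  n_samp <- ncol(gt)
  keep_rows <- list()
  ids <- character(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alt <- fix[i, "ALT"]
    calls <- gt[i, ]
    biallelic <- !is.na(alt) && !grepl(",", alt, fixed = TRUE)
    phased <- all(grepl("|", calls, fixed = TRUE)) && !any(grepl("/", calls, fixed = TRUE))
    if (!biallelic || !phased) {
      n_skipped <- n_skipped + 1L
      next
    }
    parts <- strsplit(calls, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      n_skipped <- n_skipped + 1L
      next
    }
    al <- suppressWarnings(as.integer(unlist(parts)))  # "." -> NA
    al <- matrix(al, nrow = 2L)                        # 2 x n_samp
    # interleave to (s1_left, s1_right, s2_left, ...) haplotype order
    hap <- as.vector(al)
    # recode so the major allele becomes 1; ties go to REF
    f_alt <- mean(hap == 1L, na.rm = TRUE)
    coded <- if (!is.nan(f_alt) && f_alt > 0.5) hap else 1L - hap
    keep_rows[[length(keep_rows) + 1L]] <- coded
    id <- fix[i, "ID"]
    if (is.na(id) || id == ".") id <- paste0(fix[i, "CHROM"], ":", fix[i, "POS"])
    ids <- c(ids, id)
  }
  if (n_skipped > 0L) {
    message(n_skipped, " site(s) skipped (multiallelic or unphased)")
  }
  if (length(keep_rows) == 0L) {
    stop("no phased biallelic sites in ", path, call. = FALSE)
  }
  entries <- do.call(cbind, keep_rows)
  samp <- colnames(gt)
  haplotype_matrix(entries,
                   sample_ids = paste0(rep(samp, each = 2L), "_", 1:2),
                   locus_ids = ids)
}
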