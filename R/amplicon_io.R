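# Amplicon reference, FASTQ pair I/O and run manifests.
#
# Coordinates are 0-based, half-open, on the amplicon forward strand,
# everywhere in the package.

# Primers of the focused FLT3-ITD PCR, as printed on the assay sheet
# (fluorophore label and triplet hyphens included).
.FLT3_FWD_PRINTED <- "5′ FAM_GCA-ATT-TAG-GTA-TGA-AAG-CCA-GC_3′"
.FLT3_REV_PRINTED <- "5′-CTT-TCA-GCA-TTT-TGA-CGG-CAA-CC-3′"

# Fixed synthetic insert between the primers (the real PCR-product sequence
# is laboratory input; this stand-in is screened so that the assembled
# amplicon has unique 12-mers throughout, no homopolymer of 5+ and no tandem
# repeat of period >= 15 at <= 1 mismatch).
.SYNTH_INSERT <- paste0(
  "AGCCTTAAATAACGAGCTTCGGGTGACATTGCACTTACTCGAGTAACCCGCGTGAGTAAGACTTATCATC",
  "ACAGCCGTTTTACGCCCTGGAGTCATAAACACAATGTACATGAGAGCCAGATATCAGTTATCTAACGTCG",
  "TGATAGAAACGGTAGGCAGAGCGCATCCATCTGAAGGATTTCCGTAAATTGATGTCAGAATCCTACTCAC",
  "TCCTTGAGAGCCGTCGACTGCGCCATCTTGGCGCACTCTAGCGGTCTCACCGCTGGGCCGCTGTATCGAC",
  "AATATCCGCGAGTGAGATTATCTCCTTTCCCCAA"
)

#' FLT3-ITD assay primers
#'
#' The forward and reverse primers of the focused FLT3-ITD PCR, as printed
#' (with fluorophore label and hyphens). [load_reference()] normalizes them
#' before matching.
#'
#' @return A list with elements `forward` and `reverse`.
#' @export
flt3_primers <- function() {
  list(forward = .FLT3_FWD_PRINTED, reverse = .FLT3_REV_PRINTED)
}

# Strip 5'/3' decorations, hyphens/underscores and a leading FAM label,
# uppercase, and validate the result as plain DNA.
normalize_primer <- function(x) {
  y <- toupper(x)
  y <- gsub("5['′]|3['′]", "", y)
  y <- gsub("[^A-Z]", "", y)
  y <- sub("^FAM", "", y)
  if (!grepl("^[ACGT]+$", y))
    stop("primer does not normalize to plain DNA: ", x, call. = FALSE)
  y
}

new_amplicon_reference <- function(sequence, primer_fwd, primer_rev,
                                   name = "amplicon", itd_window = NULL) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence))
    stop("reference sequence must contain only A/C/G/T", call. = FALSE)
  fwd <- normalize_primer(primer_fwd)
  rev <- normalize_primer(primer_rev)
  rev_rc <- as.character(revcomp_cpp(rev))
  if (!startsWith(sequence, fwd))
    stop("forward primer not found at the start of the reference sequence",
         call. = FALSE)
  if (!endsWith(sequence, rev_rc))
    stop("reverse complement of the reverse primer not found at the end of ",
         "the reference sequence", call. = FALSE)
  n <- nchar(sequence)
  if (is.null(itd_window))
    itd_window <- c(nchar(fwd), n - nchar(rev))
  itd_window <- as.integer(itd_window)
  if (itd_window[1] < 0L || itd_window[2] > n || itd_window[1] >= itd_window[2])
    stop("itd_window must be a half-open interval inside [0, ", n, ")",
         call. = FALSE)
  structure(
    list(name = name, sequence = sequence,
         forward_primer = primer_fwd, reverse_primer = primer_rev,
         fwd = fwd, rev = rev, itd_window = itd_window),
    class = "amplicon_reference"
  )
}

#' Load an amplicon reference from a FASTA file
#'
#' Reads a single-record FASTA, locates the primers (after stripping any
#' fluorophore label and hyphens and uppercasing; the reverse primer is
#' reverse-complemented for matching) and sets the coordinate frame. The ITD
#' reporting window defaults to the region strictly between the primers.
#'
#' @param fasta_path Path to a FASTA file containing exactly one sequence.
#' @param primer_fwd,primer_rev Primer strings as printed (decorations are
#'   tolerated). Defaults: the FLT3 assay primers, [flt3_primers()].
#' @param itd_window Optional integer pair: 0-based half-open interval on the
#'   amplicon within which insertion sites are reported.
#'
#' @return An `amplicon_reference` object.
#' @examples
#' ref <- default_reference()
#' ref$itd_window
#' @export
load_reference <- function(fasta_path,
                           primer_fwd = .FLT3_FWD_PRINTED,
                           primer_rev = .FLT3_REV_PRINTED,
                           itd_window = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1L)
    stop("reference FASTA must contain exactly one sequence, found ",
         length(ss), call. = FALSE)
  new_amplicon_reference(as.character(ss[[1]]), primer_fwd, primer_rev,
                         name = sub("\\s.*$", "", names(ss)[1]),
                         itd_window = itd_window)
}

#' Built-in synthetic amplicon reference
#'
#' A 360-bp synthetic stand-in for the FLT3-ITD PCR product: the assay
#' primers flanking a fixed synthetic insert (the package does not ship the
#' biological amplicon sequence; supply your own FASTA to [load_reference()]
#' for real data). The same sequence is available as a FASTA file under
#' `system.file("extdata", "synthetic_flt3_amplicon.fasta", package = "itdseq")`.
#'
#' @return An `amplicon_reference` object.
#' @export
default_reference <- function() {
  fwd <- normalize_primer(.FLT3_FWD_PRINTED)
  rev <- normalize_primer(.FLT3_REV_PRINTED)
  seqc <- paste0(fwd, .SYNTH_INSERT, as.character(revcomp_cpp(rev)))
  new_amplicon_reference(seqc, .FLT3_FWD_PRINTED, .FLT3_REV_PRINTED,
                         name = "FLT3_amplicon_synthetic")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat("Amplicon reference:", x$name, "\n")
  cat("  length:", nchar(x$sequence), "bp\n")
  cat("  primers:", x$fwd, "/", x$rev, "\n")
  cat("  ITD window: [", x$itd_window[1], ", ", x$itd_window[2], ")\n",
      sep = "")
  invisible(x)
}

# ---- FASTQ pairs -----------------------------------------------------------

fastq_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

parse_fastq <- function(path) {
  con <- fastq_connection(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("malformed FASTQ in '", path, "': truncated record at line ",
         4L * (n %/% 4L) + 1L, call. = FALSE)
  if (n == 0L)
    return(list(id = character(0), seq = character(0), qual = character(0)))
  hd <- lines[seq(1L, n, by = 4L)]
  sq <- lines[seq(2L, n, by = 4L)]
  pl <- lines[seq(3L, n, by = 4L)]
  ql <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop("malformed FASTQ in '", path, "': expected '@' header at line ",
         (bad[1] - 1L) * 4L + 1L, call. = FALSE)
  bad <- which(!startsWith(pl, "+"))
  if (length(bad))
    stop("malformed FASTQ in '", path, "': expected '+' separator at line ",
         (bad[1] - 1L) * 4L + 3L, call. = FALSE)
  sq <- toupper(sq)
  bad <- which(!grepl("^[ACGTN]*$", sq))
  if (length(bad))
    stop("malformed FASTQ in '", path, "': non-DNA characters at line ",
         (bad[1] - 1L) * 4L + 2L, call. = FALSE)
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop("malformed FASTQ in '", path, "': sequence/quality length mismatch ",
         "at line ", (bad[1] - 1L) * 4L + 4L, call. = FALSE)
  id <- sub("^@", "", hd)
  id <- sub("\\s.*$", "", id)
  id <- sub("/[12]$", "", id)
  list(id = id, seq = sq, qual = ql)
}

new_read_pairs <- function(read_id, seq1, qual1, seq2, qual2) {
  structure(list(read_id = read_id, seq1 = seq1, qual1 = qual1,
                 seq2 = seq2, qual2 = qual2),
            class = "read_pairs")
}

#' Construct read pairs in memory
#'
#' @param read_id Character vector of read identifiers (shared by mates).
#' @param seq1,seq2 DNA strings of mate 1 / mate 2.
#' @param qual1,qual2 Phred-33 quality strings; default constant Q40.
#' @return A `read_pairs` object.
#' @export
make_read_pairs <- function(read_id, seq1, seq2, qual1 = NULL, qual2 = NULL) {
  if (is.null(qual1)) qual1 <- strrep("I", nchar(seq1))
  if (is.null(qual2)) qual2 <- strrep("I", nchar(seq2))
  stopifnot(length(read_id) == length(seq1), length(seq1) == length(seq2),
            all(nchar(seq1) == nchar(qual1)),
            all(nchar(seq2) == nchar(qual2)))
  new_read_pairs(read_id, toupper(seq1), qual1, toupper(seq2), qual2)
}

#' @export
length.read_pairs <- function(x) length(x$read_id)

#' @export
print.read_pairs <- function(x, ...) {
  cat("read_pairs:", length(x), "pairs\n")
  invisible(x)
}

#' Read a FASTQ pair
#'
#' Reads two FASTQ files (plain or gzipped, Phred-33) whose mates are in
#' matching order. Mate counts that differ, or mate ids that disagree at some
#' record, are hard errors naming the offending record; malformed records are
#' hard errors naming the line.
#'
#' @param path1,path2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A `read_pairs` object.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- parse_fastq(path1)
  r2 <- parse_fastq(path2)
  n1 <- length(r1$id); n2 <- length(r2$id)
  if (n1 != n2)
    stop("mate count mismatch: '", path1, "' has ", n1, " records but '",
         path2, "' has ", n2, "; first unpaired record is record ",
         min(n1, n2) + 1L, call. = FALSE)
  if (n1 > 0L) {
    bad <- which(r1$id != r2$id)
    if (length(bad))
      stop("mate id mismatch at record ", bad[1], ": '", r1$id[bad[1]],
           "' vs '", r2$id[bad[1]], "'", call. = FALSE)
  }
  new_read_pairs(r1$id, r1$seq, r1$qual, r2$seq, r2$qual)
}

#' Write a FASTQ pair
#'
#' Inverse of [read_fastq_pair()]: writing then re-reading reproduces ids,
#' sequences and qualities exactly.
#'
#' @param pairs A `read_pairs` object.
#' @param path1,path2 Output paths (gzipped when ending in `.gz`).
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(pairs, path1, path2) {
  stopifnot(inherits(pairs, "read_pairs"))
  write_one <- function(path, seq, qual) {
    con <- fastq_connection(path, "wt")
    on.exit(close(con))
    writeLines(as.vector(rbind(paste0("@", pairs$read_id), seq, "+", qual)),
               con)
  }
  write_one(path1, pairs$seq1, pairs$qual1)
  write_one(path2, pairs$seq2, pairs$qual2)
  invisible(c(path1, path2))
}

# ---- Run manifest ----------------------------------------------------------

.MANIFEST_ROLES <- c("diagnosis", "followup", "control", "negative")

validate_manifest <- function(m) {
  req <- c("run_id", "sample_id", "patient_id", "timepoint",
           "fastq1", "fastq2", "role")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(m) == 0L)
    stop("manifest contains no samples", call. = FALSE)
  bad <- setdiff(unique(m$role), .MANIFEST_ROLES)
  if (length(bad))
    stop("unknown sample roles: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.MANIFEST_ROLES, collapse = ", "), ")",
         call. = FALSE)
  if (anyDuplicated(m$sample_id))
    stop("sample_id values must be unique (each sample belongs to exactly ",
         "one run)", call. = FALSE)
  m$timepoint <- as.numeric(m$timepoint)
  m
}

#' Read a run manifest
#'
#' A tab-separated sample table with columns `run_id`, `sample_id`,
#' `patient_id`, `timepoint` (numeric order within a patient), `fastq1`,
#' `fastq2`, and `role` (one of diagnosis, followup, control, negative).
#' Sample ids must be globally unique.
#'
#' @param path Path to the TSV file.
#' @return A validated data frame.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  validate_manifest(m)
}
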