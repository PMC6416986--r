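#' Construct a genome object
#'
#' A genome is a named set of chromosome sequences plus the name of the
#' chromosome that serves as the unmethylated bisulfite-conversion control
#' (in plants, the chloroplast).
#'
#' @param sequences Named character vector of nucleotide sequences
#'   (alphabet A, C, G, T, N; case-insensitive, stored uppercase).
#' @param chloroplast Name of the chloroplast sequence; must be one of
#'   `names(sequences)`.
#' @return An object of class `"genome"`: a list with elements `sequences`
#'   (named uppercase character vector) and `chloroplast`.
#' @examples
#' g <- genome(c(Chr1 = "ACGTACGT", ChrC = "ATATCGAT"), chloroplast = "ChrC")
#' @export
genome <- function(sequences, chloroplast) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named")
  sequences <- toupper(unlist(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence alphabet must be A/C/G/T/N; offending chromosome: ",
         names(sequences)[bad][1L])
  if (!chloroplast %in% names(sequences))
    stop("chloroplast '", chloroplast, "' not among sequence names")
  structure(list(sequences = sequences, chloroplast = chloroplast),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$sequences), "sequence(s),",
      sum(nchar(x$sequences)), "bp total; chloroplast =", x$chloroplast, "\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A [genome()] object.
#' @return Named integer vector of sequence lengths.
#' @export
seq_lengths <- function(genome) {
  vapply(genome$sequences, nchar, integer(1))
}

#' Read a genome from a FASTA file
#'
#' Multi-record, wrapped-line FASTA is handled by [Biostrings::readDNAStringSet()].
#'
#' @param path Path to a FASTA file.
#' @param chloroplast Name of the record to treat as the chloroplast control.
#' @return A [genome()] object.
#' @export
read_genome_fasta <- function(path, chloroplast) {
  dss <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; keep the first token as the name
  nm <- vapply(strsplit(names(dss), "\\s+"), `[`, character(1), 1L)
  genome(stats::setNames(as.character(dss), nm), chloroplast = chloroplast)
}

#' Write a genome to a FASTA file
#' @param genome A [genome()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequences), path)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a nucleotide string
#' @param seq Character vector of sequences (A/C/G/T/N).
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Classify contexts from the two downstream bases (already strand-oriented).
# CG needs only the first downstream base; CHG/CHH need both. Missing bases
# (beyond the sequence end) come in as NA.
.context_from_downstream <- function(n1, n2) {
  ctx <- rep("UNKNOWN", length(n1))
  h <- c("A", "C", "T")
  cg <- !is.na(n1) & n1 == "G"
  ctx[cg] <- "CG"
  informative <- !is.na(n1) & !is.na(n2) & n1 %in% h & n2 != "N"
  ctx[informative & n2 == "G"] <- "CHG"
  ctx[informative & n2 %in% h] <- "CHH"
  ctx
}

#' Classify the sequence context of a cytosine
#'
#' Plant cytosine methylation is described in three sequence contexts: CG,
#' CHG and CHH, where H is A, C or T. The context of a cytosine is read
#' 5'->3' on its own strand: a reverse-strand cytosine (a G on the forward
#' sequence) takes its downstream bases from the complements of the
#' positions to its left.
#'
#' @param genome A [genome()] object.
#' @param chrom Chromosome name.
#' @param pos 0-based position(s) on the forward coordinate system.
#' @param strand `"+"` or `"-"` (recycled to the length of `pos`).
#' @return Character vector: `"CG"`, `"CHG"`, `"CHH"` or `"UNKNOWN"`.
#'   `"UNKNOWN"` means the bases needed for the decision run off the
#'   sequence or are N.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  if (!chrom %in% names(genome$sequences)) stop("unknown chromosome: ", chrom)
  s <- genome$sequences[[chrom]]
  n <- nchar(s)
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= n)) stop("position out of range for ", chrom)
  strand <- rep_len(strand, length(pos))
  base_at <- function(p) {
    out <- rep(NA_character_, length(p))
    ok <- which(p >= 0L & p < n)
    if (length(ok)) out[ok] <- substring(s, p[ok] + 1L, p[ok] + 1L)
    out
  }
  b <- base_at(pos)
  fwd <- strand == "+"
  if (any(fwd & b != "C") || any(!fwd & b != "G"))
    stop("base is not a cytosine on the requested strand")
  n1 <- n2 <- rep(NA_character_, length(pos))
  n1[fwd] <- base_at(pos[fwd] + 1L)
  n2[fwd] <- base_at(pos[fwd] + 2L)
  n1[!fwd] <- unname(COMPLEMENT[base_at(pos[!fwd] - 1L)])
  n2[!fwd] <- unname(COMPLEMENT[base_at(pos[!fwd] - 2L)])
  .context_from_downstream(n1, n2)
}

#' Enumerate every cytosine site of a genome on both strands
#'
#' Every C on the forward strand and every G position (a cytosine on the
#' reverse strand) is emitted once with its context. Sites are sorted by
#' (chrom, pos, strand), with `"+"` before `"-"`.
#'
#' @param genome A [genome()] object.
#' @return A data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`.
#' @export
enumerate_cytosine_sites <- function(genome) {
  per_chrom <- lapply(names(genome$sequences), function(chrom) {
    b <- strsplit(genome$sequences[[chrom]], "", fixed = TRUE)[[1]]
    n <- length(b)
    at <- function(i) ifelse(i >= 1L & i <= n, b[pmax(pmin(i, n), 1L)], NA)
    pf <- which(b == "C")
    pr <- which(b == "G")
    df <- rbind(
      data.frame(pos = pf - 1L, strand = rep("+", length(pf)),
                 context = .context_from_downstream(at(pf + 1L), at(pf + 2L)),
                 stringsAsFactors = FALSE),
      data.frame(pos = pr - 1L, strand = rep("-", length(pr)),
                 context = .context_from_downstream(
                   unname(COMPLEMENT[at(pr - 1L)]),
                   unname(COMPLEMENT[at(pr - 2L)])),
                 stringsAsFactors = FALSE)
    )
    df$chrom <- rep(chrom, nrow(df))
    df[order(df$pos, df$strand), c("chrom", "pos", "strand", "context")]
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  out
}

#' Tabulate cytosine context frequencies
#'
#' @param sites A site data.frame as from [enumerate_cytosine_sites()].
#' @return Named integer vector with counts for CG, CHG, CHH and UNKNOWN;
#'   the counts sum to `nrow(sites)`.
#' @export
context_frequencies <- function(sites) {
  lev <- c("CG", "CHG", "CHH", "UNKNOWN")
  tab <- table(factor(sites$context, levels = lev))
  stats::setNames(as.integer(tab), lev)
}

#' Write a cytosine site table as TSV
#'
#' Columns `chrom`, `pos` (1-based, CX-report style), `strand`, `context`.
#'
#' @param sites Site data.frame (0-based `pos` internally).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  out <- sites
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
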