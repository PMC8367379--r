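# TSV dialects: long-form count tables, variant tables, results tables.
# gzip transparency comes free with R connections. Floats are written with
# 6 significant digits so file diffs are reproducible.

#' Write / read an allele-count matrix as long-form TSV
#'
#' Columns: gene, timepoint, allele (`ref`/`alt`), count.
#'
#' @param x an [AlleleCounts-class] object.
#' @param path output (input) path; `.gz` is handled transparently.
#' @return `writeAlleleCounts` returns `path` invisibly;
#'   `readAlleleCounts` returns an `AlleleCounts`.
#' @export
writeAlleleCounts <- function(x, path) {
  long <- rbind(
    data.frame(gene = rep(rownames(x), ncol(x)),
               timepoint = rep(samplingTimes(x), each = nrow(x)),
               allele = "ref", count = as.vector(refCounts(x))),
    data.frame(gene = rep(rownames(x), ncol(x)),
               timepoint = rep(samplingTimes(x), each = nrow(x)),
               allele = "alt", count = as.vector(altCounts(x))))
  write.table(long, gzfileIf(path, "w"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Unopened connection for .gz paths; write.table/read.delim open and close
# (and flush) it themselves.
gzfileIf <- function(path, mode = "") {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' @rdname writeAlleleCounts
#' @param hybrid hybrid label for the returned object.
#' @export
readAlleleCounts <- function(path, hybrid = "hybrid") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "timepoint", "allele", "count")
  if (!all(need %in% colnames(df)))
    stop("malformed count table ", path, ": need columns ",
         paste(need, collapse = ", "))
  bad <- which(is.na(suppressWarnings(as.numeric(df$count))) |
                 !(df$allele %in% c("ref", "alt")))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1, " of ", path)
  tps <- sort(unique(df$timepoint))
  genes <- unique(df$gene)
  shape <- function(allele) {
    sub <- df[df$allele == allele, ]
    m <- matrix(0, length(genes), length(tps),
                dimnames = list(genes, paste0("t", tps)))
    m[cbind(match(sub$gene, genes), match(sub$timepoint, tps))] <- sub$count
    m
  }
  AlleleCounts(shape("ref"), shape("alt"), timepoints = tps,
               hybrid = hybrid)
}

#' Write / read CRE barcode counts as long-form TSV
#'
#' Columns: barcode, sample, count; RNA samples are named `rna_t<i>`, DNA
#' samples `dna_<j>`.
#'
#' @param x a [CreCounts-class] object.
#' @param path file path.
#' @param manifest manifest to attach on read.
#' @return `writeCreCounts` returns `path` invisibly; `readCreCounts` a
#'   `CreCounts`.
#' @export
writeCreCounts <- function(x, path) {
  wide <- cbind(rnaCounts(x), dnaCounts(x))
  long <- data.frame(barcode = rep(rownames(wide), ncol(wide)),
                     sample = rep(colnames(wide), each = nrow(wide)),
                     count = as.vector(wide))
  write.table(long, gzfileIf(path, "w"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeCreCounts
#' @export
readCreCounts <- function(path, manifest) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "sample", "count")
  if (!all(need %in% colnames(df)))
    stop("malformed CRE count table ", path)
  bad <- which(is.na(suppressWarnings(as.numeric(df$count))))
  if (length(bad)) stop("malformed row at line ", bad[1] + 1, " of ", path)
  samples <- unique(df$sample)
  bcs <- unique(df$barcode)
  m <- matrix(0, length(bcs), length(samples),
              dimnames = list(bcs, samples))
  m[cbind(match(df$barcode, bcs), match(df$sample, samples))] <- df$count
  rna <- m[, grepl("^rna_", samples), drop = FALSE]
  dna <- m[, grepl("^dna_", samples), drop = FALSE]
  CreCounts(rna, dna, manifest,
            time = as.numeric(sub("^rna_t", "", colnames(rna))))
}

#' Write / read a library manifest CSV
#'
#' @param manifest data.frame as produced by [designLibrary()].
#' @param path CSV path.
#' @export
writeManifest <- function(manifest, path) {
  write.table(as.data.frame(manifest), path, sep = ",", quote = TRUE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a variant table
#'
#' The native dialect is TSV with columns chrom, pos (1-based), ref, alt,
#' type (SNP/INS/DEL). `readVariants` also accepts a minimal VCF (CHROM,
#' POS, REF, ALT; the type is inferred from allele lengths).
#'
#' @param variants data.frame of variants.
#' @param path file path; a `.vcf` suffix or a `##fileformat` header
#'   triggers VCF parsing on read.
#' @export
writeVariants <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeVariants
#' @export
readVariants <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\\.vcf(\\.gz)?$", path) || startsWith(first, "##")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    lines[1] <- sub("^#", "", lines[1])
    df <- read.delim(text = paste(lines, collapse = "\n"),
                     stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    out <- data.frame(chrom = df$chrom, pos = as.integer(df$pos),
                      ref = df$ref, alt = df$alt)
    out$type <- ifelse(nchar(out$ref) == nchar(out$alt), "SNP",
                       ifelse(nchar(out$ref) < nchar(out$alt), "INS",
                              "DEL"))
    return(out)
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "type")
  if (!all(need %in% colnames(df)))
    stop("malformed variant table ", path)
  df
}

#' Write / read genome FASTA
#'
#' Thin wrappers over Biostrings.
#'
#' @param genome a `DNAStringSet`.
#' @param path FASTA path.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write / read GFF3 annotations
#'
#' 1-based closed coordinates on disk (the GFF3 convention), `GRanges` in
#' memory. The `tss` attribute round-trips as an integer metadata column.
#'
#' @param annotation a `GRanges` with `type`, `ID` and optionally `tss`
#'   metadata columns.
#' @param path GFF3 path.
#' @export
writeGff3 <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "gff3")
  invisible(path)
}

#' @rdname writeGff3
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(gr$tss)) gr$tss <- as.integer(gr$tss)
  gr
}

#' Read a bedGraph score track
#'
#' @param path bedGraph path (0-based half-open on disk; returned as a
#'   1-based `GRanges` with a `score` column).
#' @export
readScoreTrack <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a results table as TSV with stable float formatting
#'
#' Numeric columns are serialized with 6 significant digits.
#'
#' @param df data.frame of results.
#' @param path TSV path.
#' @export
writeResultsTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmtNum(out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
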