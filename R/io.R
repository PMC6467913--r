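# Readers and writers. Internal coordinates are 0-based half-open
# throughout; conversion to 1-based happens only at the VCF boundary.

#' Write / read a Strand-seq composite file as BED-like TSV
#'
#' Columns: chrom, pos, pos+1, orientation, haplotag.
#'
#' @param reads Oriented-read tibble.
#' @param path Output path.
#' @return `path` (writer) or the reads tibble (reader), invisibly/visibly.
#' @export
write_composite_tsv <- function(reads, path) {
  utils::write.table(
    data.frame(reads$chrom, reads$pos, reads$pos + 1, reads$orientation,
               reads$haplotag),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_composite_tsv
#' @export
read_composite_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos", "pos1", "orientation",
                                        "haplotag"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "character"))
  as_tibble(df) |> select(-"pos1") |> arrange(.data$chrom, .data$pos)
}

#' Write an SV callset as BED-like TSV
#'
#' @param calls Call tibble with `chrom`, `start`, `end`, `type`, `sv_len`
#'   and optionally `genotype`, `caller`.
#' @param path Output path.
#' @export
write_sv_bed <- function(calls, path) {
  cols <- intersect(c("chrom", "start", "end", "type", "sv_len", "genotype",
                      "caller"), names(calls))
  utils::write.table(as.data.frame(calls[, cols]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an SV callset as minimal VCF 4.2
#'
#' Symbolic ALT alleles (`<DEL>`, `<INS>`, `<DUP>`, `<INV>`) with
#' `SVTYPE`/`SVLEN`/`END` INFO keys and a `GT` sample column. `SVLEN` is
#' negative for deletions per convention. POS is 1-based.
#'
#' @param calls Call tibble (`chrom`, `start`, `end`, `type`, `sv_len`,
#'   optional `genotype`).
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @export
write_sv_vcf <- function(calls, path, sample = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  gt <- if ("genotype" %in% names(calls)) calls$genotype else "./."
  svlen <- round(abs(calls$sv_len)) * if_else(calls$type == "DEL", -1, 1)
  rows <- sprintf(
    "%s\t%d\t%s\t%s\t<%s>\t.\tPASS\tSVTYPE=%s;SVLEN=%d;END=%d\tGT\t%s",
    calls$chrom, as.integer(calls$start + 1),
    if ("call_id" %in% names(calls)) calls$call_id else
      sprintf("sv%d", seq_len(nrow(calls))),
    "N", calls$type, calls$type, as.integer(svlen), as.integer(calls$end),
    gt)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an SV callset from VCF or BED-like TSV
#'
#' Coordinates are normalised to 0-based half-open. For VCF, `SVTYPE`,
#' `SVLEN` and `END` are reconciled (negative `SVLEN` for deletions per
#' convention); records where `END` contradicts `SVLEN` for a deletion are
#' rejected with a record-level warning naming the line, and parsing
#' continues.
#'
#' @param path Input path.
#' @param dialect `"vcf"` or `"bed_tsv"`.
#' @return Call tibble: `call_id`, `chrom`, `start`, `end`, `type`,
#'   `sv_len`, `genotype`.
#' @export
read_sv_callset <- function(path, dialect = c("vcf", "bed_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "bed_tsv") {
    df <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      colClasses = NA))
    if (!"genotype" %in% names(df)) df$genotype <- NA_character_
    if (!"call_id" %in% names(df)) {
      df$call_id <- sprintf("sv%d", seq_len(nrow(df)))
    }
    return(select(df, dplyr::any_of(c("call_id", "chrom", "start", "end",
                                      "type", "sv_len", "genotype", "caller"))))
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svlen <- as.numeric(vcfR::extract.info(v, "SVLEN"))
  endv <- as.numeric(vcfR::extract.info(v, "END"))
  gt <- if (ncol(v@gt) >= 2) {
    vapply(strsplit(v@gt[, 2], ":"), `[`, character(1), 1)
  } else rep(NA_character_, nrow(fix))
  pos1 <- as.numeric(fix$POS)
  start0 <- pos1 - 1
  end0 <- if_else(is.na(endv),
                  if_else(svtype == "INS", start0 + 1, start0 + abs(svlen)),
                  endv)
  bad <- !is.na(endv) & svtype == "DEL" &
    abs((endv - start0) - abs(svlen)) > 1
  if (any(bad)) {
    for (i in which(bad)) {
      warn(sprintf("record %d (%s:%s): END inconsistent with SVLEN; skipped.",
                   i, fix$CHROM[i], fix$POS[i]))
    }
  }
  tibble(call_id = fix$ID, chrom = fix$CHROM, start = start0, end = end0,
         type = svtype, sv_len = abs(svlen), genotype = gt)[!bad, ]
}

#' Read a BED annotation track
#'
#' @param path BED path (chrom, start, end in the first three columns).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed_track <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  as_tibble(df)
}

#' Write a BED annotation track
#'
#' @param track Tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_bed_track <- function(track, path) {
  utils::write.table(as.data.frame(track[, c("chrom", "start", "end")]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
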