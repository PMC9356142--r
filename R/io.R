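# File I/O for the standard formats (FASTA, GFF3, VCF, TSV/JSON) and the
# run configuration document. Readers are gzip-transparent (via the
# underlying packages/connections). External 1-based inclusive coordinates
# (GFF3, VCF) are converted to internal 0-based half-open at the parser
# boundary.

#' Read a (multi-contig) genome FASTA
#'
#' @param path FASTA path (plain or gzip).
#' @return Named character vector of uppercase contig sequences; names are
#'   the first whitespace-delimited token of each header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path))
    stop("I/O error: FASTA not readable: ", path, call. = FALSE)
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- vapply(strsplit(names(dss), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Write a genome FASTA (60-column wrapped)
#'
#' @param seqs Named character vector of contig sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Read a GFF3 annotation
#'
#' @param path GFF3 path.
#' @return A `GRanges` (1-based inclusive, as in the file) with at least a
#'   `type` metadata column.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path))
    stop("I/O error: GFF3 not readable: ", path, call. = FALSE)
  rtracklayer::import(path, format = "gff3")
}

#' Write a GFF3 annotation
#'
#' @param features Data frame with columns `seqid`, `source`, `type`,
#'   `start`, `end` (1-based inclusive), `strand`, and optional attribute
#'   columns (`ID`, `gene_id`, `transcript_id`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand)
  meta <- features[, setdiff(names(features),
                             c("seqid", "start", "end", "strand")),
                   drop = FALSE]
  for (nm in names(meta)) S4Vectors::mcols(gr)[[nm]] <- meta[[nm]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a VCF into a minimal variant table
#'
#' Keeps the fields the variant scan uses (CHROM, POS, ID, REF, ALT).
#' Multi-allelic records are split into one row per ALT.
#'
#' @param path VCF path (plain or gzip).
#' @return Data frame with columns `CHROM`, `POS` (1-based), `ID`, `REF`,
#'   `ALT`.
#' @export
read_vcf_df <- function(path) {
  if (!file.exists(path))
    stop("I/O error: VCF not readable: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i] %||% "", ",")[[1]]
    for (alt in alts)
      out[[length(out) + 1L]] <- data.frame(
        CHROM = fix$CHROM[i], POS = as.integer(fix$POS[i]),
        ID = fix$ID[i], REF = fix$REF[i], ALT = alt,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(CHROM = character(0), POS = integer(0),
                      ID = character(0), REF = character(0),
                      ALT = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write a minimal VCF 4.2 file
#'
#' @param variants Data frame with columns `CHROM`, `POS` (1-based), `ID`,
#'   `REF`, `ALT`.
#' @param path Output path.
#' @param contig_lengths Optional named integer vector for contig header
#'   lines.
#' @return Invisibly, `path`.
#' @export
write_vcf_df <- function(variants, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=editcascade")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  variants$CHROM, variants$POS, variants$ID,
                  variants$REF, variants$ALT)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' All module configurations under one document, as used by the command-line
#' interface and the scan pipelines.
#'
#' @return Nested list of defaults.
#' @export
run_config_defaults <- function() {
  list(
    predictor = "bundled",
    predictor_params = unclass(predictor_params()),
    filter_config = unclass(filter_config()),
    search_config = unclass(search_config()),
    sim_config = unclass(sim_config()),
    scan = list(window_half_width = NULL, step = 1L, dedup_radius = 5L,
                donor_insertion = "GAT", variant_direction = "install"))
}

.merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys take their documented defaults.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- run_config_defaults()
  if (is.null(path)) return(defaults)
  if (!file.exists(path))
    stop("I/O error: config not readable: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  .merge_config(defaults, user)
}

# rebuild classed configs from a plain config list
.config_objects <- function(config) {
  list(
    predictor = config$predictor,
    params = do.call(predictor_params, config$predictor_params),
    filters = do.call(filter_config, config$filter_config),
    cfg = do.call(search_config, config$search_config),
    sim = do.call(sim_config, config$sim_config),
    scan = config$scan)
}
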