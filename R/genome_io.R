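#' Construct a genome record
#'
#' A `GenomeRecord` holds one replicon: its identifier, upper-case A/C/G/T/N
#' sequence, length, and topology. Multi-replicon assemblies are represented
#' as lists of records sharing an `assembly_id`.
#'
#' @param replicon_id replicon identifier (unique within a run).
#' @param sequence DNA string; lower case is up-cased, any symbol outside
#'   A/C/G/T/N is mapped to N with a warning.
#' @param topology `"circular"` or `"linear"`.
#' @param organism_label,assembly_id optional metadata.
#' @return an object of class `GenomeRecord`.
#' @export
genome_record <- function(replicon_id, sequence,
                          topology = c("linear", "circular"),
                          organism_label = NA_character_,
                          assembly_id = NA_character_) {
  topology <- match.arg(topology)
  s <- sanitize_dna(sequence)
  if (s$n_mapped > 0)
    warning(sprintf("replicon '%s': %d non-ACGTN characters mapped to N",
                    replicon_id, s$n_mapped))
  structure(list(replicon_id = replicon_id, sequence = s$seq,
                 length = nchar(s$seq), topology = topology,
                 organism_label = organism_label, assembly_id = assembly_id),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("<GenomeRecord %s: %s nt, %s%s>\n", x$replicon_id,
              format(x$length, big.mark = ","), x$topology,
              if (!is.na(x$assembly_id)) paste0(", assembly ", x$assembly_id) else ""))
  invisible(x)
}

#' Load genomes from FASTA or GenBank
#'
#' Reads one `GenomeRecord` per sequence record. FASTA is parsed with
#' Biostrings; for GenBank flat files only the LOCUS line (id, topology) and
#' ORIGIN sequence block are used — the pipeline is sequence-driven and gene
#' features are ignored.
#'
#' @param path input file (FASTA `.fa/.fasta/.fna` or GenBank `.gb/.gbk/.gbff`;
#'   format is sniffed from content when the extension is ambiguous).
#' @param topology_default topology assigned when the file does not state one.
#' @param assembly_id optional assembly label attached to every record.
#' @return a named list of `GenomeRecord` (names = replicon ids).
#' @export
load_genomes <- function(path, topology_default = c("linear", "circular"),
                         assembly_id = NA_character_) {
  topology_default <- match.arg(topology_default)
  if (!file.exists(path)) stop("cannot read genome file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty genome file: ", path)
  if (grepl("^LOCUS", first)) {
    recs <- read_genbank_seq(path, topology_default, assembly_id)
  } else {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L) stop("no sequence records in ", path)
    ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
    recs <- lapply(seq_along(ss), function(i) {
      genome_record(ids[i], as.character(ss[[i]]), topology_default,
                    assembly_id = assembly_id)
    })
    names(recs) <- ids
  }
  if (anyDuplicated(names(recs)))
    stop("duplicate replicon ids in ", path)
  recs
}

# Minimal GenBank reader: LOCUS line for id/topology, ORIGIN block for
# sequence.  Feature tables are deliberately not parsed.
read_genbank_seq <- function(path, topology_default, assembly_id) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("no LOCUS record in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  recs <- lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    loc <- strsplit(block[1L], "\\s+")[[1L]]
    id <- loc[2L]
    topo <- if (any(grepl("circular", block[1L], ignore.case = TRUE)))
      "circular" else if (any(grepl("linear", block[1L], ignore.case = TRUE)))
      "linear" else topology_default
    org <- grep("^\\s+ORGANISM\\s+", block, value = TRUE)
    org <- if (length(org)) sub("^\\s+ORGANISM\\s+", "", org[1L]) else NA_character_
    oi <- grep("^ORIGIN", block)
    if (length(oi) == 0L) stop("GenBank record ", id, " has no ORIGIN block")
    seqlines <- block[(oi[1L] + 1L):length(block)]
    seqlines <- seqlines[!grepl("^//", seqlines)]
    seq <- gsub("[0-9 /]", "", paste(seqlines, collapse = ""))
    genome_record(id, seq, topo, organism_label = org, assembly_id = assembly_id)
  })
  names(recs) <- vapply(recs, `[[`, "", "replicon_id")
  recs
}

#' Load rho-independent terminator annotations
#'
#' Reads a tab-delimited table with columns `replicon_id`, `strand`,
#' `stem_start`, `stem_end`, `term_3prime` and optionally `shape` (L/I).
#' Coordinates are 1-based inclusive in the file and converted to the
#' package's 0-based half-open convention. Rows violating `stem_start <
#' stem_end` or falling outside a supplied replicon are skipped with a
#' warning; a missing shape column yields `shape = "unknown"`.
#'
#' @param path TSV file.
#' @param genomes optional named list of `GenomeRecord` for bounds checking.
#' @return data.frame of terminator records (0-based half-open `stem_start`,
#'   `stem_end`; `term_3prime` is a 0-based position).
#' @export
load_terminators <- function(path, genomes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("replicon_id", "strand", "stem_start", "stem_end", "term_3prime")
  if (!all(need %in% names(df)))
    stop("terminator table must have columns: ", paste(need, collapse = ", "))
  if (!"shape" %in% names(df)) df$shape <- "unknown"
  df$shape[is.na(df$shape) | !df$shape %in% c("L", "I")] <- "unknown"
  # file is 1-based inclusive
  df$stem_start <- as.integer(df$stem_start) - 1L
  df$stem_end <- as.integer(df$stem_end)
  df$term_3prime <- as.integer(df$term_3prime) - 1L
  bad <- df$stem_start >= df$stem_end
  # on the + strand the terminator 3' end lies at/after the stem; mirrored on -
  bad <- bad | ifelse(df$strand == "+", df$term_3prime < df$stem_end - 1L,
                      df$term_3prime > df$stem_start)
  if (!is.null(genomes)) {
    lens <- vapply(genomes, `[[`, 0L, "length")
    known <- df$replicon_id %in% names(lens)
    inside <- known
    inside[known] <- df$stem_start[known] >= 0L &
      df$stem_end[known] <= lens[df$replicon_id[known]] &
      df$term_3prime[known] >= 0L &
      df$term_3prime[known] < lens[df$replicon_id[known]]
    bad <- bad | !inside
  }
  if (any(bad))
    warning(sum(bad), " terminator row(s) skipped (invalid coordinates)")
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export intron calls to GFF3 or TSV
#'
#' GFF3 uses 1-based inclusive coordinates, feature type
#' `mobile_genetic_element`, and carries category / IEP type / IEP status in
#' the attribute column. TSV writes one row per call with the same 1-based
#' coordinates.
#'
#' @param calls data.frame of intron calls (see [call_introns()]).
#' @param path output file.
#' @param format `"gff3"` or `"tsv"`.
#' @param genomes optional named list of `GenomeRecord`; when supplied, calls
#'   referencing unknown replicons are an error.
#' @return `path`, invisibly.
#' @export
export_calls <- function(calls, path, format = c("gff3", "tsv"), genomes = NULL) {
  format <- match.arg(format)
  if (!is.null(genomes) && nrow(calls) > 0 &&
      !all(calls$replicon_id %in% names(genomes)))
    stop("calls reference unknown replicon id(s): ",
         paste(setdiff(calls$replicon_id, names(genomes)), collapse = ", "))
  if (format == "tsv") {
    out <- calls
    if (nrow(out) > 0) {
      out$start <- out$start + 1L  # 1-based inclusive on disk
      out <- out[, setdiff(names(out), "d1_4"), drop = FALSE]
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (nrow(calls) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = calls$replicon_id,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    strand = calls$strand)
  S4Vectors::mcols(gr)$source <- "g2iscan"
  S4Vectors::mcols(gr)$type <- "mobile_genetic_element"
  S4Vectors::mcols(gr)$score <- calls$dvvi_bits
  S4Vectors::mcols(gr)$ID <- calls$call_id
  S4Vectors::mcols(gr)$category <- calls$category
  S4Vectors::mcols(gr)$iep_type <- ifelse(is.na(calls$iep_type), "none", calls$iep_type)
  S4Vectors::mcols(gr)$iep_status <-
    ifelse(is.na(calls$iep_status), "none", calls$iep_status)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Re-import intron calls written by [export_calls()]
#'
#' @param path GFF3 or TSV file.
#' @param format file format.
#' @return data.frame with 0-based half-open coordinates, strand, category,
#'   IEP type and status (the round-trippable core of a call table).
#' @export
import_calls <- function(path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (nrow(df) > 0) df$start <- df$start - 1L
    return(df)
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- data.frame(
    call_id = as.character(S4Vectors::mcols(gr)$ID),
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    category = as.character(S4Vectors::mcols(gr)$category),
    iep_type = as.character(S4Vectors::mcols(gr)$iep_type),
    iep_status = as.character(S4Vectors::mcols(gr)$iep_status),
    stringsAsFactors = FALSE)
  df$iep_type[df$iep_type == "none"] <- NA_character_
  df$iep_status[df$iep_status == "none"] <- NA_character_
  df
}
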