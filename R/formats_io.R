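# Readers and writers for the external file dialects the pipeline
# touches. Internal coordinates are always 0-based half-open
# (BED-native); GFF files are 1-based inclusive and converted at the
# boundary only.

MISO_REQUIRED_COLS <- c("event_name", "sample1_psi_mean", "sample2_psi_mean",
                        "diff", "bayes_factor")

#' Read a MISO-style comparison table
#'
#' Parses the tab-separated comparison dialect (one row per event with
#' PSI posterior means for the two samples, their difference, a Bayes
#' factor, and per-sample inclusion/exclusion counts). Columns are
#' looked up by name, so column order and extra columns are tolerated.
#' Rows with a non-numeric Bayes factor or PSI are skipped with a
#' warning; the number of skipped rows is attached as attribute
#' `n_skipped`.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return Tibble of comparison records; attribute `n_skipped` counts
#'   dropped rows. Event names are kept as opaque keys (coordinates
#'   embedded in them are not reinterpreted).
#' @export
read_miso_comparison <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(MISO_REQUIRED_COLS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("Malformed line %d in %s: %s",
                  prob$row[1] + 1L, path, prob$expected[1]))
  }
  num_cols <- setdiff(names(raw), "event_name")
  parsed <- raw %>%
    mutate(across(all_of(num_cols), ~ suppressWarnings(as.numeric(.x))))
  bad <- !is.finite(parsed$bayes_factor) | !is.finite(parsed$sample1_psi_mean) |
    !is.finite(parsed$sample2_psi_mean) | !is.finite(parsed$diff)
  if (any(bad)) {
    warn(sprintf("Skipped %d row(s) with non-numeric BF/PSI in %s",
                 sum(bad), path))
  }
  out <- parsed[!bad, ]
  if (any(out$bayes_factor < 0)) abort("Negative Bayes factor encountered.")
  off <- abs(out$diff - (out$sample1_psi_mean - out$sample2_psi_mean))
  if (any(off > 1e-6)) {
    abort(sprintf("Row %d: diff does not equal sample1 - sample2 PSI.",
                  which(off > 1e-6)[1]))
  }
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write a MISO-style comparison table
#'
#' Inverse of [read_miso_comparison()]: writes records field-for-field
#' as a tab-separated file with header.
#'
#' @param records Tibble of comparison records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_miso_comparison <- function(records, path) {
  assert_columns(records, MISO_REQUIRED_COLS, "`records`")
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read transcription-factor footprints from a BED6+ file
#'
#' BED coordinates are 0-based half-open and kept as-is. The name
#' column is the motif identifier; the score column holds the binding
#' posterior probability (in [0, 1]). When the posterior/score column
#' is absent the posterior defaults to 1 with a warning. An optional
#' seventh column `binding_effect` (values `affecting`/`neutral`) is
#' preserved when present.
#'
#' @param path Path to a headerless BED file (>= 4 columns).
#' @return Tibble with `chrom`, `start`, `end`, `motif_id`,
#'   `posterior`, `strand` (and `binding_effect` when present).
#' @export
read_footprints_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  motif_id = character(), posterior = numeric(),
                  strand = character()))
  }
  if (ncol(raw) < 4) abort("Footprint BED needs at least 4 columns.")
  out <- tibble(
    chrom = raw[[1]],
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    motif_id = raw[[4]]
  )
  if (ncol(raw) >= 5) {
    out$posterior <- as.numeric(raw[[5]])
  } else {
    warn("No posterior column; defaulting posterior to 1.0.")
    out$posterior <- 1
  }
  out$strand <- if (ncol(raw) >= 6) raw[[6]] else "."
  if (ncol(raw) >= 7) out$binding_effect <- raw[[7]]
  if (any(out$start >= out$end)) {
    abort(sprintf("Interval with start >= end at line %d.",
                  which(out$start >= out$end)[1]))
  }
  if (any(out$posterior < 0 | out$posterior > 1, na.rm = TRUE)) {
    abort("Posterior outside [0, 1].")
  }
  out
}

#' Write footprints as BED6(+)
#'
#' @param footprints Tibble with `chrom`, `start`, `end`, `motif_id`,
#'   `posterior`, `strand` (optionally `binding_effect`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_footprints_bed <- function(footprints, path) {
  assert_columns(footprints, c("chrom", "start", "end", "motif_id",
                               "posterior", "strand"), "`footprints`")
  cols <- c("chrom", "start", "end", "motif_id", "posterior", "strand")
  if ("binding_effect" %in% names(footprints)) cols <- c(cols, "binding_effect")
  readr::write_tsv(footprints[, cols], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read event annotations from a GFF3 file
#'
#' Expects the event-annotation dialect: one `gene` feature per event
#' carrying `ID` and `event_type` attributes, one `mRNA` feature per
#' isoform (two isoforms for every type except TandemUTR), and one
#' `exon` per isoform describing its alternative terminal/unit block.
#' On-disk coordinates are 1-based inclusive (GFF3) and converted to
#' the internal 0-based half-open convention; for AFE events the TSS of
#' each isoform is the first transcribed base of its first exon.
#'
#' @param path Path to a GFF3 file.
#' @return Annotation tibble with `event_id`, `gene_id`, `event_type`,
#'   `chrom`, `strand`, `iso1_start`, `iso1_end`, `iso2_start`,
#'   `iso2_end` (internal coordinates).
#' @export
read_event_gff <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID),
    parent = vapply(as.list(gr$Parent), function(p)
      if (length(p) == 0) NA_character_ else as.character(p[1]), character(1)),
    event_type = if ("event_type" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$event_type) else NA_character_,
    gene_id = if ("gene_id" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$gene_id) else NA_character_
  )
  genes <- df %>% filter(type == "gene")
  if (any(!genes$event_type %in% EVENT_TYPES)) {
    bad <- setdiff(unique(genes$event_type), EVENT_TYPES)
    abort(sprintf("Unknown event type(s) in GFF: %s",
                  paste(bad, collapse = ", ")))
  }
  mrna <- df %>% filter(type == "mRNA")
  exons <- df %>% filter(type == "exon")
  purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    isos <- mrna %>% filter(parent == g$id) %>% arrange(id)
    if (nrow(isos) < 2 && g$event_type != "TandemUTR") {
      abort(sprintf("Event %s (%s) has %d isoform(s); two required.",
                    g$id, g$event_type, nrow(isos)))
    }
    iso_block <- function(iso_id) {
      ex <- exons %>% filter(parent == iso_id)
      if (nrow(ex) == 0) return(c(NA_real_, NA_real_))
      c(min(ex$start), max(ex$end))
    }
    b1 <- if (nrow(isos) >= 1) iso_block(isos$id[1]) else c(NA_real_, NA_real_)
    b2 <- if (nrow(isos) >= 2) iso_block(isos$id[2]) else c(NA_real_, NA_real_)
    tibble(
      event_id = g$id,
      gene_id = if (is.na(g$gene_id)) g$id else g$gene_id,
      event_type = g$event_type,
      chrom = g$chrom, strand = g$strand,
      iso1_start = b1[1], iso1_end = b1[2],
      iso2_start = b2[1], iso2_end = b2[2]
    )
  }) %>% list_rbind()
}

#' Write event annotations as GFF3
#'
#' Inverse of [read_event_gff()]: emits a `gene` feature per event with
#' `event_type` attribute and one `mRNA` + `exon` pair per isoform
#' block, converting internal 0-based half-open coordinates back to
#' 1-based inclusive GFF3.
#'
#' @param annotation Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_gff <- function(annotation, path) {
  assert_columns(annotation, c("event_id", "event_type", "chrom", "strand",
                               "iso1_start", "iso1_end"), "`annotation`")
  rows <- purrr::map(seq_len(nrow(annotation)), function(i) {
    a <- annotation[i, ]
    blocks <- list(c(a$iso1_start, a$iso1_end))
    # The exclusion isoform of SE/RI/A3SS/A5SS/MXE has no alternative
    # block of its own: it is written as an mRNA without an exon child.
    if (!is.null(a$iso2_start) && !is.na(a$iso2_start)) {
      blocks <- c(blocks, list(c(a$iso2_start, a$iso2_end)))
    } else if (a$event_type != "TandemUTR") {
      blocks <- c(blocks, list(NULL))
    }
    span <- range(unlist(blocks))
    gene <- tibble(chrom = a$chrom, start = span[1], end = span[2],
                   strand = a$strand, type = "gene", id = a$event_id,
                   parent = NA_character_, event_type = a$event_type,
                   gene_id = a$gene_id)
    iso <- purrr::map(seq_along(blocks), function(j) {
      iso_id <- sprintf("%s.iso%d", a$event_id, j)
      blk <- blocks[[j]]
      mrna <- tibble(chrom = a$chrom,
                     start = if (is.null(blk)) span[1] else blk[1],
                     end = if (is.null(blk)) span[2] else blk[2],
                     strand = a$strand, type = "mRNA", id = iso_id,
                     parent = a$event_id, event_type = NA_character_,
                     gene_id = NA_character_)
      if (is.null(blk)) return(mrna)
      bind_rows(
        mrna,
        tibble(chrom = a$chrom, start = blk[1], end = blk[2],
               strand = a$strand, type = "exon",
               id = sprintf("%s.exon", iso_id), parent = iso_id,
               event_type = NA_character_, gene_id = NA_character_)
      )
    }) %>% list_rbind()
    bind_rows(gene, iso)
  }) %>% list_rbind()
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start + 1, end = rows$end),
    strand = rows$strand
  )
  gr$type <- rows$type
  gr$ID <- rows$id
  gr$Parent <- ifelse(is.na(rows$parent), "", rows$parent)
  gr$event_type <- rows$event_type
  gr$gene_id <- rows$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
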