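#' Read a BED-like interval file
#'
#' Reads tab-separated intervals in BED convention (0-based half-open).
#' Lines starting with `#`, `track` or `browser` are skipped. The first
#' six columns are named `chrom, start, end, name, score, strand` as
#' present; any further columns are preserved with their positional
#' names.
#'
#' @param path Path to the file.
#' @param min_cols Minimum number of tab-separated fields each data line
#'   must carry (default 3).
#' @return A tibble of intervals, one row per BED line.
#' @export
read_bed <- function(path, min_cols = 3) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  is_data <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  data_lines <- lines[is_data]
  if (length(data_lines) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer()
    ))
  }
  nf <- lengths(strsplit(data_lines, "\t", fixed = TRUE))
  if (any(nf < min_cols)) {
    bad <- which(is_data)[which(nf < min_cols)[1]]
    stop(sprintf(
      "Line %d has %d fields; at least %d required.",
      bad, nf[which(nf < min_cols)[1]], min_cols
    ))
  }
  # pad ragged lines so every row carries the full column set
  if (min(nf) < max(nf)) {
    data_lines <- paste0(data_lines, strrep("\t", max(nf) - nf))
  }
  tbl <- readr::read_tsv(
    I(data_lines),
    col_names = paste0("X", seq_len(max(nf))),
    col_types = readr::cols(
      X1 = readr::col_character(),
      X2 = readr::col_double(),
      X3 = readr::col_double(),
      .default = readr::col_guess()
    ),
    # comma is a list separator in BED12 block columns, never grouping
    locale = readr::locale(grouping_mark = " "),
    progress = FALSE
  )
  std <- c("chrom", "start", "end", "name", "score", "strand")
  n_std <- min(ncol(tbl), length(std))
  names(tbl)[seq_len(n_std)] <- std[seq_len(n_std)]
  tbl$start <- as.integer(tbl$start)
  tbl$end <- as.integer(tbl$end)
  validate_intervals(tbl, where = path)
  tbl
}

# shared interval sanity checks (0-based half-open)
validate_intervals <- function(tbl, where = "intervals") {
  if (any(tbl$start < 0)) {
    stop(sprintf("%s: negative start coordinate.", where))
  }
  if (any(tbl$end <= tbl$start)) {
    i <- which(tbl$end <= tbl$start)[1]
    stop(sprintf(
      "%s: empty or inverted interval at row %d (start %d, end %d).",
      where, i, tbl$start[i], tbl$end[i]
    ))
  }
  invisible(tbl)
}

#' Write intervals to a BED file
#'
#' Columns beyond `chrom, start, end` are written in their current order,
#' so `read_bed(write_bed(x))` round-trips.
#'
#' @param intervals Tibble with at least `chrom, start, end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  readr::write_tsv(intervals, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a narrowPeak file
#'
#' ENCODE narrowPeak is BED6+4; the four extra columns are named
#' `signal_value, p_value, q_value, peak`.
#'
#' @param path Path to the file.
#' @return Tibble with 10 named columns.
#' @export
read_narrowpeak <- function(path) {
  tbl <- read_bed(path, min_cols = 10)
  names(tbl)[7:10] <- c("signal_value", "p_value", "q_value", "peak")
  tbl
}

#' Read a bedGraph file
#'
#' @param path Path to the file.
#' @return Tibble with `chrom, start, end, score`.
#' @export
read_bedgraph <- function(path) {
  tbl <- read_bed(path, min_cols = 4)
  names(tbl)[4] <- "score"
  tbl$score <- as.numeric(tbl$score)
  tbl
}

#' Read gene models from GTF or BED12
#'
#' Coordinates are normalized to the package-wide 0-based half-open
#' convention (GTF input is 1-based inclusive). The transcription start
#' site is strand-resolved: `tss = start` on `+`, `end - 1` on `-`;
#' `tx_end` is the opposite extremity. Records with unknown strand are
#' dropped with a warning; an exon outside its gene span is an error.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @return Tibble with columns `gene_id, chrom, start, end, strand, tss,
#'   tx_end` and a list-column `exons` of tibbles (`start, end`), sorted
#'   and non-overlapping.
#' @export
read_gene_models <- function(path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    if (!"gene_id" %in% names(md)) {
      stop("GTF lacks a gene_id attribute.")
    }
    feat <- tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      # GTF is 1-based inclusive; internal is 0-based half-open
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      type = as.character(md$type),
      gene_id = as.character(md$gene_id)
    )
    genes <- dplyr::filter(feat, .data$type == "gene")
    if (nrow(genes) == 0) { # fall back to exon extents
      genes <- feat |>
        dplyr::filter(.data$type == "exon") |>
        dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
        dplyr::summarise(
          start = min(.data$start), end = max(.data$end),
          .groups = "drop"
        )
    }
    exons <- dplyr::filter(feat, .data$type == "exon")
    out <- genes |>
      dplyr::select("gene_id", "chrom", "start", "end", "strand") |>
      dplyr::mutate(exons = purrr::map(
        .data$gene_id,
        function(g) {
          ex <- exons[exons$gene_id == g, c("start", "end")]
          if (nrow(ex) == 0) ex <- genes[genes$gene_id == g, c("start", "end")]
          dplyr::arrange(tibble::as_tibble(ex), .data$start)
        }
      ))
  } else {
    tbl <- read_bed(path, min_cols = 12)
    names(tbl)[7:12] <- c(
      "thick_start", "thick_end", "item_rgb",
      "block_count", "block_sizes", "block_starts"
    )
    parse_blocks <- function(start, sizes, starts) {
      sz <- as.integer(strsplit(as.character(sizes), ",")[[1]])
      of <- as.integer(strsplit(as.character(starts), ",")[[1]])
      st <- start + of
      dplyr::arrange(tibble::tibble(start = st, end = st + sz), .data$start)
    }
    out <- tibble::tibble(
      gene_id = as.character(tbl$name),
      chrom = tbl$chrom,
      start = tbl$start,
      end = tbl$end,
      strand = tbl$strand,
      exons = purrr::pmap(
        list(tbl$start, tbl$block_sizes, tbl$block_starts), parse_blocks
      )
    )
  }
  bad_strand <- !out$strand %in% c("+", "-")
  if (any(bad_strand)) {
    warning(sprintf(
      "Dropped %d gene model(s) with unknown strand.", sum(bad_strand)
    ))
    out <- out[!bad_strand, ]
  }
  ok <- purrr::pmap_lgl(
    list(out$exons, out$start, out$end),
    function(ex, s, e) all(ex$start >= s & ex$end <= e & ex$end > ex$start)
  )
  if (any(!ok)) {
    stop(sprintf(
      "Exon outside gene span for gene(s): %s",
      paste(out$gene_id[!ok], collapse = ", ")
    ))
  }
  add_tss(out)
}

# strand-resolved TSS / transcription end (0-based positions)
add_tss <- function(genes) {
  dplyr::mutate(
    genes,
    tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
    tx_end = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
  )
}

#' Read a replicate expression table
#'
#' Expects a header line with a `gene_id` column plus the named replicate
#' columns for each tissue. Values may be linear intensities (set
#' `log_transform = TRUE`) or already log2. The expression difference is
#' `delta_e = mean(log2 tissue1) - mean(log2 tissue2)`. Genes with a
#' missing replicate value are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @param tissue1_cols,tissue2_cols Character vectors of replicate column
#'   names for each tissue.
#' @param log_transform If `TRUE`, values are log2-transformed on read
#'   (all values must then be positive).
#' @return Tibble with `gene_id`, list-columns `log2_reps_tissue1` and
#'   `log2_reps_tissue2`, and `delta_e`.
#' @export
read_expression_table <- function(path, tissue1_cols, tissue2_cols,
                                  log_transform = FALSE) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("gene_id", tissue1_cols, tissue2_cols)
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    stop(sprintf("Missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  reps <- as.matrix(tbl[, c(tissue1_cols, tissue2_cols)])
  complete <- stats::complete.cases(reps)
  if (any(!complete)) {
    warning(sprintf(
      "Dropped %d gene(s) with missing replicate values.", sum(!complete)
    ))
    tbl <- tbl[complete, ]
    reps <- reps[complete, , drop = FALSE]
  }
  if (log_transform) {
    if (any(reps <= 0)) {
      stop("Non-positive expression value under log_transform.")
    }
    reps <- log2(reps)
  }
  n1 <- length(tissue1_cols)
  expression_records(
    gene_id = as.character(tbl$gene_id),
    log2_reps_tissue1 = asplit(reps[, seq_len(n1), drop = FALSE], 1),
    log2_reps_tissue2 = asplit(reps[, n1 + seq_along(tissue2_cols), drop = FALSE], 1)
  )
}

#' Build expression records from replicate lists
#'
#' @param gene_id Character vector of gene identifiers.
#' @param log2_reps_tissue1,log2_reps_tissue2 Lists of numeric replicate
#'   vectors (log2 scale), one per gene.
#' @return Tibble with `delta_e = mean(tissue1) - mean(tissue2)`.
#' @export
expression_records <- function(gene_id, log2_reps_tissue1, log2_reps_tissue2) {
  stopifnot(
    length(gene_id) == length(log2_reps_tissue1),
    length(gene_id) == length(log2_reps_tissue2),
    all(lengths(log2_reps_tissue1) > 0),
    all(lengths(log2_reps_tissue2) > 0)
  )
  tibble::tibble(
    gene_id = gene_id,
    log2_reps_tissue1 = lapply(log2_reps_tissue1, as.numeric),
    log2_reps_tissue2 = lapply(log2_reps_tissue2, as.numeric),
    delta_e = vapply(log2_reps_tissue1, mean, numeric(1)) -
      vapply(log2_reps_tissue2, mean, numeric(1))
  )
}

#' Read an enhancer-promoter map
#'
#' @param path TSV with columns `enhancer_chrom, enhancer_start,
#'   enhancer_end, target_gene_id` (0-based half-open coordinates).
#' @return Tibble with `chrom, start, end, target_gene_id`.
#' @export
read_enhancer_map <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("enhancer_chrom", "enhancer_start", "enhancer_end", "target_gene_id")
  if (!all(need %in% names(tbl))) {
    stop(sprintf("Enhancer map needs columns: %s", paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(
    chrom = as.character(tbl$enhancer_chrom),
    start = as.integer(tbl$enhancer_start),
    end = as.integer(tbl$enhancer_end),
    target_gene_id = as.character(tbl$target_gene_id)
  )
  validate_intervals(out, where = path)
  out
}

#' Read a gene-to-term annotation map
#'
#' @param path TSV with columns `gene_id, term_id` and optionally
#'   `term_name`.
#' @return Tibble with one row per (gene, term) annotation.
#' @export
read_gene2go <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(tbl))) {
    stop("gene2go map needs columns gene_id and term_id.")
  }
  if (!"term_name" %in% names(tbl)) tbl$term_name <- tbl$term_id
  tibble::as_tibble(tbl[, c("gene_id", "term_id", "term_name")])
}

# tibble (chrom/start/end[/strand]) -> GRanges; internal 0-based half-open
# becomes 1-based closed inside GRanges.
as_granges <- function(tbl, use_strand = FALSE) {
  strand <- if (use_strand && "strand" %in% names(tbl)) {
    tbl$strand
  } else {
    rep("*", nrow(tbl))
  }
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand
  )
}

granges_to_tibble <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}
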