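#' Read a per-sample methylation call table
#'
#' Parses per-cytosine read counts from either the MethylDackel-style
#' bedGraph dialect (six columns: chromosome, 0-based start, end, methylation
#' percentage, methylated count, unmethylated count; an optional leading
#' `track` line is skipped; the percentage column is ignored in favour of the
#' counts) or a generic TSV with header `chrom, pos, n_meth, n_unmeth`.
#'
#' All coordinates in the returned tibble are 0-based.
#'
#' @param path Path to the table.
#' @param dialect `"methyldackel"` or `"tsv"`.
#' @param region Optional region restriction, either a string
#'   `"chrom:start-end"` (0-based half-open) or a list with elements `chrom`,
#'   `start`, `end`. Region queries require coordinate-sorted input.
#' @param sample_id Optional sample label attached as an attribute.
#' @return A tibble with columns `chrom`, `pos`, `n_meth`, `n_unmeth`.
#' @export
read_methylation_table <- function(path,
                                   dialect = c("methyldackel", "tsv"),
                                   region = NULL, sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "methyldackel") {
    first <- readLines(path, n = 1)
    skip <- if (length(first) == 1 && grepl("^track", first)) 1 else 0
    tbl <- suppressWarnings(readr::read_tsv(
      path, skip = skip, col_names = c("chrom", "pos", "end", "pct",
                                       "n_meth", "n_unmeth"),
      col_types = readr::cols(
        chrom = readr::col_character(), pos = readr::col_integer(),
        end = readr::col_integer(), pct = readr::col_double(),
        n_meth = readr::col_integer(), n_unmeth = readr::col_integer()
      ),
      progress = FALSE
    ))
    .raise_parse_problems(tbl, path)
    tbl <- dplyr::select(tbl, "chrom", "pos", "n_meth", "n_unmeth")
  } else {
    tbl <- suppressWarnings(readr::read_tsv(
      path,
      col_types = readr::cols(
        chrom = readr::col_character(), pos = readr::col_integer(),
        n_meth = readr::col_integer(), n_unmeth = readr::col_integer()
      ),
      progress = FALSE
    ))
    .raise_parse_problems(tbl, path)
    miss <- setdiff(c("chrom", "pos", "n_meth", "n_unmeth"), names(tbl))
    if (length(miss) > 0) {
      stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    tbl <- dplyr::select(tbl, "chrom", "pos", "n_meth", "n_unmeth")
  }
  if (any(is.na(tbl$pos) | is.na(tbl$n_meth) | is.na(tbl$n_unmeth))) {
    bad <- which(is.na(tbl$pos) | is.na(tbl$n_meth) | is.na(tbl$n_unmeth))[1]
    stop("malformed row at line ", bad, " of ", path, call. = FALSE)
  }
  if (any(tbl$n_meth < 0 | tbl$n_unmeth < 0)) {
    stop("negative read counts in ", path, call. = FALSE)
  }
  if (!is.null(region)) {
    region <- .parse_region(region)
    sorted <- !is.unsorted(order(tbl$chrom, tbl$pos), strictly = FALSE) &&
      !is.unsorted(tbl$pos[tbl$chrom == region$chrom])
    if (!sorted) {
      stop("index required: input is not coordinate-sorted but a region ",
           "query was requested", call. = FALSE)
    }
    tbl <- dplyr::filter(tbl, .data$chrom == region$chrom,
                         .data$pos >= region$start, .data$pos < region$end)
  }
  if (!is.null(sample_id)) attr(tbl, "sample_id") <- sample_id
  tbl
}

.raise_parse_problems <- function(tbl, path) {
  pr <- readr::problems(tbl)
  if (nrow(pr) > 0) {
    stop("malformed row at line ", pr$row[1], " of ", path, ": ",
         pr$expected[1], " expected", call. = FALSE)
  }
}

.parse_region <- function(region) {
  if (is.character(region) && length(region) == 1) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("cannot parse region: ", region, call. = FALSE)
    region <- list(chrom = m[2], start = as.integer(m[3]),
                   end = as.integer(m[4]))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  region
}

#' Write a per-sample methylation call table
#'
#' Inverse of [read_methylation_table()]; used mainly to materialise
#' simulated populations on disk.
#'
#' @param tbl Tibble with columns `chrom`, `pos`, `n_meth`, `n_unmeth`.
#' @param path Output path.
#' @param dialect `"methyldackel"` or `"tsv"`.
#' @export
write_methylation_table <- function(tbl, path,
                                    dialect = c("methyldackel", "tsv")) {
  dialect <- match.arg(dialect)
  .check_sites(tbl, c("chrom", "pos", "n_meth", "n_unmeth"))
  tbl <- dplyr::arrange(tbl, .data$chrom, .data$pos)
  if (dialect == "methyldackel") {
    cov <- tbl$n_meth + tbl$n_unmeth
    out <- tibble::tibble(
      chrom = tbl$chrom, start = tbl$pos, end = tbl$pos + 1L,
      pct = round(100 * tbl$n_meth / pmax(cov, 1)),
      n_meth = tbl$n_meth, n_unmeth = tbl$n_unmeth
    )
    readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  } else {
    readr::write_tsv(tbl[, c("chrom", "pos", "n_meth", "n_unmeth")], path,
                     progress = FALSE)
  }
  invisible(path)
}

#' Assign the sequence context of cytosines
#'
#' For each genomic position, returns the plant methylation context of the
#' cytosine there: `CG`, `CHG` or `CHH` (H = A, C or T). A position holding
#' `C` is read on the forward strand (the two following bases decide the
#' context); a position holding `G` is a cytosine on the reverse strand and
#' the two preceding bases decide the context on the reverse complement.
#' Positions that are not a cytosine on either strand, that run off the
#' sequence end before the context is resolved, or whose deciding bases are
#' ambiguous, get `"none"`.
#'
#' @param genome A named `character` vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based positions (same length as `chrom`).
#' @param strand Optional strand vector (`"+"`/`"-"`); when `NULL` (default)
#'   the strand is inferred from the base at the position.
#' @return Character vector with values in `c("CG", "CHG", "CHH", "none")`.
#' @export
assign_context <- function(genome, chrom, pos, strand = NULL) {
  seqs <- .genome_as_character(genome)
  stopifnot(length(chrom) == length(pos))
  if (!all(chrom %in% names(seqs))) {
    stop("unknown chromosome(s): ",
         paste(setdiff(unique(chrom), names(seqs)), collapse = ", "),
         call. = FALSE)
  }
  lens <- vapply(seqs, nchar, integer(1))
  if (any(pos < 0 | pos >= lens[chrom])) {
    stop("position out of sequence bounds", call. = FALSE)
  }
  base_at <- function(offset) {
    p <- pos + offset
    ok <- p >= 0 & p < lens[chrom]
    b <- rep(NA_character_, length(pos))
    if (any(ok)) {
      b[ok] <- substring(seqs[chrom[ok]], p[ok] + 1, p[ok] + 1)
    }
    b
  }
  b0 <- base_at(0L)
  fwd <- b0 == "C"
  rev <- b0 == "G"
  if (!is.null(strand)) {
    fwd <- fwd & strand == "+"
    rev <- rev & strand == "-"
  }
  up1 <- base_at(1L); up2 <- base_at(2L)    # forward-strand neighbours
  dn1 <- base_at(-1L); dn2 <- base_at(-2L)  # reverse-strand neighbours
  is_h <- function(b) !is.na(b) & b %in% c("A", "C", "T")
  out <- rep("none", length(pos))
  # forward: C G -> CG; C H G -> CHG; C H H -> CHH
  out[fwd & !is.na(up1) & up1 == "G"] <- "CG"
  chg <- fwd & is_h(up1) & !is.na(up2) & up2 == "G"
  chh <- fwd & is_h(up1) & is_h(up2)
  out[chg] <- "CHG"
  out[chh] <- "CHH"
  # reverse: read on the complement; preceding C -> CG, etc.
  out[rev & !is.na(dn1) & dn1 == "C"] <- "CG"
  is_h_rev <- function(b) !is.na(b) & b %in% c("A", "G", "T")  # complement in H
  rchg <- rev & is_h_rev(dn1) & !is.na(dn2) & dn2 == "C"
  rchh <- rev & is_h_rev(dn1) & is_h_rev(dn2)
  out[rchg] <- "CHG"
  out[rchh] <- "CHH"
  out
}

.genome_as_character <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("`genome` must be named", call. = FALSE)
    return(genome)
  }
  stop("`genome` must be a named character vector or a DNAStringSet",
       call. = FALSE)
}

#' Tabulate every cytosine of a genome with its context
#'
#' @inheritParams assign_context
#' @return A tibble with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`.
#' @export
context_table <- function(genome) {
  seqs <- .genome_as_character(genome)
  purrr::map_dfr(names(seqs), function(ch) {
    s <- seqs[[ch]]
    cpos <- as.integer(gregexpr("C", s, fixed = TRUE)[[1]])
    gpos <- as.integer(gregexpr("G", s, fixed = TRUE)[[1]])
    cpos <- cpos[cpos > 0] - 1L
    gpos <- gpos[gpos > 0] - 1L
    tbl <- tibble::tibble(
      chrom = ch,
      pos = c(cpos, gpos),
      strand = rep(c("+", "-"), c(length(cpos), length(gpos)))
    )
    tbl <- dplyr::arrange(tbl, .data$pos)
    tbl$context <- assign_context(seqs, tbl$chrom, tbl$pos, tbl$strand)
    tbl
  })
}

#' Write per-site scan statistics
#'
#' Writes a coordinate-sorted site-statistics table either as a full TSV
#' (all columns, 6-decimal round-trip fidelity) or as a single-signal
#' bedGraph track of JSD or MET.
#'
#' @param stats Site-statistics tibble as returned by [scan_methylomes()].
#' @param path Output path.
#' @param format `"tsv"`, `"bedgraph_jsd"`, or `"bedgraph_met"`.
#' @export
write_site_stats <- function(stats, path,
                             format = c("tsv", "bedgraph_jsd",
                                        "bedgraph_met")) {
  format <- match.arg(format)
  .check_sites(stats, c("chrom", "pos"))
  stats <- dplyr::arrange(stats, .data$chrom, .data$pos)
  if (anyDuplicated(stats[, c("chrom", "pos")]) > 0) {
    stop("duplicate coordinates in site statistics", call. = FALSE)
  }
  if (format == "tsv") {
    readr::write_tsv(stats, path, progress = FALSE)
  } else {
    col <- if (format == "bedgraph_jsd") "jsd" else "met"
    out <- tibble::tibble(chrom = stats$chrom, start = stats$pos,
                          end = stats$pos + 1L,
                          value = round(stats[[col]], 6))
    writeLines(sprintf("track type=bedGraph name=%s", col), path)
    readr::write_tsv(out, path, col_names = FALSE, append = TRUE,
                     progress = FALSE)
  }
  invisible(path)
}

#' Read back a site-statistics TSV written by [write_site_stats()]
#'
#' @param path Path to the TSV.
#' @return A tibble; the `ctype` column (if present) is restored as a factor.
#' @export
read_site_stats <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), .default = readr::col_guess()
  ), progress = FALSE)
  if ("ctype" %in% names(tbl)) {
    tbl$ctype <- factor(tbl$ctype, levels = c("LMC", "HMC", "MMC", "MSC"))
  }
  tbl
}

#' Read gene/element annotations from BED or GFF3
#'
#' Delegates parsing to `rtracklayer::import()` and converts everything to
#' the package's 0-based half-open convention (GFF3's 1-based closed
#' coordinates are shifted here and nowhere else).
#'
#' @param path Path to a BED or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"`, or `"gff3"`.
#' @param category_field For GFF3, the column or attribute holding the
#'   feature category (default `"type"`); for BED the category defaults to
#'   `NA` unless `category_field` names an imported column.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `id`,
#'   `category`.
#' @export
read_features <- function(path, format = c("auto", "bed", "gff3"),
                          category_field = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3"
                            else "bed")
  md <- as.data.frame(S4Vectors::mcols(gr))
  id <- if (format == "gff3") {
    if ("ID" %in% names(md)) as.character(md$ID)
    else if ("Name" %in% names(md)) as.character(md$Name)
    else as.character(seq_along(gr))
  } else {
    if ("name" %in% names(md)) as.character(md$name)
    else as.character(seq_along(gr))
  }
  cat_field <- category_field %||% if (format == "gff3") "type" else NULL
  category <- if (!is.null(cat_field) && cat_field %in% names(md)) {
    as.character(md[[cat_field]])
  } else NA_character_
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = id,
    category = category
  )
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  .check_features(out)
  out
}

#' Read a genomic segmentation with signed eigenvalues
#'
#' Expects a TSV with header `chrom, start, end, eigen`; negative eigenvalues
#' mark compacted structural domains (CSD), positive ones loose domains
#' (LSD).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `chrom`, `start`, `end`, `eigen`.
#' @export
read_segmentation <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), eigen = readr::col_double()
  ), progress = FALSE)
  .check_features(tbl, "segmentation")
  tbl
}
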