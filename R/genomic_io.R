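#' @useDynLib chromnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats phyper ppois p.adjust rbinom rpois rgeom runif rnorm
#'   setNames cor hclust cutree as.dist sd wilcox.test quantile aggregate
#' @importFrom utils read.table write.table head combn
NULL

# All coordinates are 0-based, half-open (BED convention). 1-based inputs
# (SNP tables) are converted at the reader boundary.

#' Genomic interval data frames
#'
#' Intervals are plain data frames with columns `chrom` (character),
#' `start`, `end` (0-based half-open integers). [genomic_intervals()]
#' validates and normalises such a data frame.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param ... further equal-length columns (e.g. `name`, `strand`) kept
#'   verbatim.
#' @return a data frame with at least `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, where = "interval set") {
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$end <= df$start)
  if (length(bad)) {
    stop(sprintf("%s: invalid interval at record %d (start=%s, end=%s)",
                 where, bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}

read_tab_lines <- function(path, min_cols, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(list(fields = list(), lineno = integer(0)))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < min_cols)) {
    i <- which(ncols < min_cols)[1]
    stop(sprintf("%s: line %d has %d column(s); at least %d required",
                 what, idx[i], ncols[i], min_cols))
  }
  list(fields = fields, lineno = idx)
}

parse_coord <- function(x, what, lineno) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop(sprintf("%s: line %d: non-integer coordinate '%s'",
                 what, lineno[bad[1]], x[bad[1]]))
  }
  v
}

#' Read a BED file
#'
#' Reads 3+ column tab-separated BED; comment (`#`), `track` and `browser`
#' lines are skipped. Coordinates are kept verbatim (0-based half-open).
#' Column 4 is returned as `name`, column 6 as `strand`, when present.
#'
#' @param path file path.
#' @return data frame of intervals (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  p <- read_tab_lines(path, 3L, "read_bed")
  if (!length(p$fields)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  chrom <- vapply(p$fields, `[`, "", 1L)
  start <- parse_coord(vapply(p$fields, `[`, "", 2L), "read_bed", p$lineno)
  end   <- parse_coord(vapply(p$fields, `[`, "", 3L), "read_bed", p$lineno)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  ncols <- lengths(p$fields)
  if (all(ncols >= 4L)) df$name <- vapply(p$fields, `[`, "", 4L)
  if (all(ncols >= 6L)) df$strand <- vapply(p$fields, `[`, "", 6L)
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad)) {
    stop(sprintf("read_bed: line %d: invalid interval [%d, %d)",
                 p$lineno[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  df
}

#' Write intervals as BED
#'
#' @param df interval data frame; optional `name`/`strand` columns are
#'   written as BED columns 4 and 6 (score column 5 filled with ".").
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, df$start, df$end)
  if (!is.null(df$name) && !is.null(df$strand)) {
    cols <- c(cols, list(df$name, rep(".", nrow(df)), df$strand))
  } else if (!is.null(df$name)) {
    cols <- c(cols, list(df$name))
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read interaction calls (BEDPE)
#'
#' Reads 6+ column BEDPE (chrom1, start1, end1, chrom2, start2, end2); an
#' optional 7th column is read as the supporting pair (PET) count, columns
#' 8 and 9 as p- and q-values when present. Anchors are canonically ordered
#' so that (chrom1, start1) <= (chrom2, start2); a missing PET column
#' defaults to 1.
#'
#' @param path file path.
#' @return data frame with columns `chrom1,start1,end1,chrom2,start2,end2,
#'   pet` (+ `p`, `q` when present).
#' @export
read_bedpe <- function(path) {
  p <- read_tab_lines(path, 6L, "read_bedpe")
  empty <- data.frame(chrom1 = character(0), start1 = integer(0),
                      end1 = integer(0), chrom2 = character(0),
                      start2 = integer(0), end2 = integer(0),
                      pet = integer(0), stringsAsFactors = FALSE)
  if (!length(p$fields)) return(empty)
  g <- function(i) vapply(p$fields, `[`, "", i)
  df <- data.frame(chrom1 = g(1L),
                   start1 = parse_coord(g(2L), "read_bedpe", p$lineno),
                   end1   = parse_coord(g(3L), "read_bedpe", p$lineno),
                   chrom2 = g(4L),
                   start2 = parse_coord(g(5L), "read_bedpe", p$lineno),
                   end2   = parse_coord(g(6L), "read_bedpe", p$lineno),
                   stringsAsFactors = FALSE)
  ncols <- lengths(p$fields)
  df$pet <- if (all(ncols >= 7L)) {
    v <- suppressWarnings(as.integer(g(7L)))
    if (anyNA(v)) stop(sprintf("read_bedpe: line %d: non-integer PET count",
                               p$lineno[which(is.na(v))[1]]))
    v
  } else rep(1L, nrow(df))
  if (all(ncols >= 9L)) {
    df$p <- as.numeric(g(8L)); df$q <- as.numeric(g(9L))
  }
  for (side in c(1, 2)) {
    s <- df[[paste0("start", side)]]; e <- df[[paste0("end", side)]]
    bad <- which(s < 0 | e <= s)
    if (length(bad)) {
      stop(sprintf("read_bedpe: line %d: invalid anchor %d interval",
                   p$lineno[bad[1]], side))
    }
  }
  canonicalize_bedpe(df)
}

canonicalize_bedpe <- function(df) {
  flip <- df$chrom2 < df$chrom1 |
    (df$chrom1 == df$chrom2 & df$start2 < df$start1)
  if (any(flip)) {
    tmp <- df[flip, c("chrom1", "start1", "end1")]
    df[flip, c("chrom1", "start1", "end1")] <-
      df[flip, c("chrom2", "start2", "end2")]
    df[flip, c("chrom2", "start2", "end2")] <- tmp
  }
  df
}

#' Write interaction calls as BEDPE
#'
#' @param df data frame from [read_bedpe()] (or with the same columns).
#' @param path output path.
#' @export
write_bedpe <- function(df, path) {
  cols <- list(df$chrom1, df$start1, df$end1, df$chrom2, df$start2, df$end2,
               df$pet)
  if (!is.null(df$p)) cols <- c(cols, list(df$p, df$q))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read regulatory-state segments (BED4)
#'
#' Column 4 must hold one of the closed state vocabulary: promoter,
#' enhancer, insulator, poised_promoter, repressed, transcribed,
#' low_signal.
#'
#' @param path file path.
#' @return interval data frame with a `state` column.
#' @export
read_states <- function(path) {
  df <- read_bed(path)
  if (is.null(df$name)) stop("read_states: state column (BED column 4) required")
  names(df)[names(df) == "name"] <- "state"
  bad <- !df$state %in% chrom_states()
  if (any(bad)) {
    stop(sprintf("read_states: unknown state '%s'", df$state[which(bad)[1]]))
  }
  df
}

#' @rdname read_states
#' @export
chrom_states <- function() {
  c("promoter", "enhancer", "insulator", "poised_promoter",
    "repressed", "transcribed", "low_signal")
}

#' Read TSS definitions (BED6-like)
#'
#' Each record is a 1-bp TSS position `[p, p+1)` with gene id in column 4
#' and strand in column 6.
#'
#' @param path file path.
#' @return data frame with `chrom,start,end,gene_id,strand`.
#' @export
read_tss <- function(path) {
  df <- read_bed(path)
  if (is.null(df$name) || is.null(df$strand)) {
    stop("read_tss: gene id (col 4) and strand (col 6) required")
  }
  names(df)[names(df) == "name"] <- "gene_id"
  if (any(df$end - df$start != 1L)) {
    stop("read_tss: TSS records must be 1 bp wide")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("read_tss: strand must be + or -")
  df
}

#' Read a SNP table
#'
#' Tab-separated with header `phenotype  chrom  pos`; positions are 1-based
#' and converted to 0-based half-open 1-bp intervals.
#'
#' @param path file path.
#' @return data frame with `phenotype,chrom,start,end`.
#' @export
read_snps <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "integer"))
  if (!all(c("phenotype", "chrom", "pos") %in% names(df))) {
    stop("read_snps: columns phenotype, chrom, pos required")
  }
  data.frame(phenotype = df$phenotype, chrom = df$chrom,
             start = df$pos - 1L, end = df$pos,
             stringsAsFactors = FALSE)
}

#' Write a SNP table (1-based positions)
#' @param df data frame from [read_snps()].
#' @param path output path.
#' @export
write_snps <- function(df, path) {
  out <- data.frame(phenotype = df$phenotype, chrom = df$chrom,
                    pos = df$start + 1L)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' Tab-separated, header line with `gene_id` then one column per cell or
#' tissue type; values are non-negative expression levels.
#'
#' @param path file path.
#' @return numeric matrix, rownames = gene ids, colnames = cell types.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("read_expression: negative expression value")
  m
}

#' Interval overlap test with symmetric extension of the first interval
#'
#' TRUE iff `a` and `b` are on the same chromosome and
#' `[a$start - extension, a$end + extension)` intersects `[b$start, b$end)`.
#' Vectorised over rows.
#'
#' @param a,b interval data frames (recycled to common length).
#' @param extension non-negative extension in bp applied to `a`.
#' @return logical vector.
#' @export
overlaps <- function(a, b, extension = 0L) {
  stopifnot(extension >= 0)
  a$chrom == b$chrom &
    (a$start - extension) < b$end &
    b$start < (a$end + extension)
}

#' Base pairs of overlap between two intervals
#'
#' @param a,b interval data frames (recycled to common length).
#' @return integer vector; 0 when disjoint or on different chromosomes.
#' @export
overlap_bp <- function(a, b) {
  w <- pmin(a$end, b$end) - pmax(a$start, b$start)
  ifelse(a$chrom == b$chrom & w > 0, w, 0L)
}

#' Genomic distance between interval midpoints
#'
#' The absolute difference of interval midpoints, in bp. `Inf` for
#' different chromosomes.
#'
#' @param a,b interval data frames.
#' @return numeric vector of distances.
#' @export
genomic_distance <- function(a, b) {
  d <- abs((a$start + a$end) / 2 - (b$start + b$end) / 2)
  ifelse(a$chrom == b$chrom, d, Inf)
}

# Bulk overlap join via the IRanges interval index: rows of `query`
# (extended both sides) x rows of `subject`. Returns data.frame(query,
# subject, bp) of overlapping pairs, where bp is the unextended overlap
# width (may be <= 0 when only the extension hits). Coordinates convert
# from 0-based half-open to the 1-based closed convention at this
# boundary only.
overlap_join <- function(query, subject, extension = 0L) {
  if (!nrow(query) || !nrow(subject)) {
    return(data.frame(query = integer(0), subject = integer(0),
                      bp = integer(0)))
  }
  q <- GenomicRanges::GRanges(query$chrom, IRanges::IRanges(
    start = pmax(0L, query$start - as.integer(extension)) + 1L,
    end = query$end + as.integer(extension)))
  s <- GenomicRanges::GRanges(subject$chrom, IRanges::IRanges(
    start = subject$start + 1L, end = subject$end))
  # disjoint chromosome sets between query and subject are a legitimate
  # no-hit case, not a user error
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  out_q <- S4Vectors::queryHits(hits)
  out_s <- S4Vectors::subjectHits(hits)
  bp <- pmin(query$end[out_q], subject$end[out_s]) -
    pmax(query$start[out_q], subject$start[out_s])
  data.frame(query = out_q, subject = out_s, bp = as.integer(bp))
}
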