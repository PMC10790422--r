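#' Construct a validated fragment table
#'
#' Fragments are single cfDNA molecules represented as 0-based half-open
#' genomic intervals (BED convention). All per-bp computations in the package
#' inherit this convention; 1-based inputs (e.g. BAM) are converted at the
#' boundary.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy `end > start`.
#' @param sample_id optional sample key attached to every fragment.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `length`,
#'   `sample_id`, sorted by (chrom, start, end).
#' @export
fragments <- function(chrom, start, end, sample_id = NA_character_) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("start and end must have equal length")
  }
  chrom <- rep_len(as.character(chrom), length(start))
  if (any(is.na(chrom) | !nzchar(chrom))) stop("chrom names must be non-empty")
  if (any(is.na(start)) || any(is.na(end))) stop("fragment coordinates must be integers")
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("invalid fragment(s) with end <= start at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  out <- data.frame(
    chrom = chrom, start = start, end = end,
    length = end - start,
    sample_id = rep_len(as.character(sample_id), length(chrom)),
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

empty_fragments <- function(sample_id = NA_character_) {
  data.frame(chrom = character(), start = integer(), end = integer(),
             length = integer(), sample_id = character(),
             stringsAsFactors = FALSE)
}

#' Read cfDNA fragments from BED, BEDPE or BAM
#'
#' One fragment per sequenced molecule. BED intervals are taken as already
#' 0-based half-open. BEDPE rows (columns 1-6) yield one fragment per read
#' pair spanning the outer coordinates of the two ends. BAM mode (requires
#' the Rsamtools package) keeps primary, properly paired, non-duplicate
#' records and forms one fragment per pair from the leftmost start to the
#' rightmost end; strand is ignored throughout.
#'
#' @param path input file.
#' @param format one of `"bed"`, `"bedpe"`, `"bam"`.
#' @param sample_id sample key attached to the fragments.
#' @return fragment `data.frame` sorted by (chrom, start, end); see
#'   [fragments()].
#' @export
read_fragments <- function(path, format = c("bed", "bedpe", "bam"),
                           sample_id = NA_character_) {
  format <- match.arg(format)
  if (format != "bam" && !file.exists(path)) stop("file not found: ", path)
  if (format == "bam") return(read_fragments_bam(path, sample_id))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_fragments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- if (format == "bed") 3L else 6L
  nf <- lengths(fields)
  if (any(nf < ncols)) {
    stop(sprintf("parse error in %s at line %d: expected >= %d tab-separated fields",
                 path, which(nf < ncols)[1], ncols))
  }
  get_col <- function(i) vapply(fields, `[[`, character(1), i)
  if (format == "bed") {
    chrom <- get_col(1)
    start <- suppressWarnings(as.integer(get_col(2)))
    end <- suppressWarnings(as.integer(get_col(3)))
    if (anyNA(start) || anyNA(end)) {
      stop(sprintf("parse error in %s at line %d: non-integer coordinate",
                   path, which(is.na(start) | is.na(end))[1]))
    }
  } else {
    c1 <- get_col(1); c2 <- get_col(4)
    if (any(c1 != c2)) {
      stop(sprintf("validation error in %s at line %d: read pair spans two chromosomes",
                   path, which(c1 != c2)[1]))
    }
    s1 <- suppressWarnings(as.integer(get_col(2)))
    e1 <- suppressWarnings(as.integer(get_col(3)))
    s2 <- suppressWarnings(as.integer(get_col(5)))
    e2 <- suppressWarnings(as.integer(get_col(6)))
    if (anyNA(s1) || anyNA(e1) || anyNA(s2) || anyNA(e2)) {
      stop(sprintf("parse error in %s at line %d: non-integer coordinate",
                   path, which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))[1]))
    }
    chrom <- c1
    start <- pmin(s1, s2)
    end <- pmax(e1, e2)
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("validation error in %s at line %d: end <= start", path, bad[1]))
  }
  fragments(chrom, start, end, sample_id)
}

read_fragments_bam <- function(path, sample_id = NA_character_) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM input requires the Rsamtools package")
  }
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isDuplicate = FALSE, isUnmappedQuery = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "isize"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  # keep the leftmost mate of each pair (positive template length)
  keep <- !is.na(res$isize) & res$isize > 0L
  if (!any(keep)) return(empty_fragments())
  fragments(as.character(res$rname[keep]),
            res$pos[keep] - 1L,              # 1-based -> 0-based
            res$pos[keep] - 1L + res$isize[keep],
            sample_id)
}

#' Write fragments as BED or BEDPE
#'
#' @param frags fragment table from [fragments()] or [read_fragments()].
#' @param path output file.
#' @param format `"bed"` or `"bedpe"`. BEDPE writes each fragment as a pair of
#'   degenerate 1-bp ends at the outer coordinates, which [read_fragments()]
#'   round-trips to the identical fragment set.
#' @export
write_fragments <- function(frags, path, format = c("bed", "bedpe")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- frags[, c("chrom", "start", "end")]
  } else {
    df <- data.frame(frags$chrom, frags$start, frags$start + 1L,
                     frags$chrom, frags$end - 1L, frags$end)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Size-filter fragments
#'
#' Keeps fragments whose length lies in the closed interval
#' `[min_len, max_len]`. The defaults are the 80-200 bp window that removes
#' sub-nucleosomal degradation products and long genomic DNA contamination
#' from normal blood cells while retaining mononucleosome-protected cfDNA.
#'
#' @param frags fragment table.
#' @param min_len,max_len inclusive bounds in bp.
#' @return the kept fragments, input order preserved.
#' @export
filter_fragments <- function(frags, min_len = 80L, max_len = 200L) {
  if (min_len < 1L) stop("min_len must be >= 1")
  if (max_len < min_len) stop("max_len must be >= min_len")
  frags[frags$length >= min_len & frags$length <= max_len, , drop = FALSE]
}

region_types <- c("cpg_marker", "tss", "pas")

#' Construct a validated target-region table
#'
#' Target regions are the capture-panel intervals: 150-bp windows around CpG
#' markers (`cpg_marker`), and TSS/PAS regions (anchor +/- 1 kb) for the
#' nucleosome-organization panel, whose `anchor` column records the TSS or
#' PAS coordinate.
#'
#' @param chrom,start,end 0-based half-open coordinates.
#' @param name unique region identifiers.
#' @param region_type one of `"cpg_marker"`, `"tss"`, `"pas"` (recycled).
#' @param anchor anchor coordinate for tss/pas regions (`NA` for cpg_marker);
#'   must satisfy `start <= anchor < end`.
#' @return `data.frame` with the six columns above.
#' @export
target_regions <- function(chrom, start, end, name,
                           region_type = "cpg_marker", anchor = NA_integer_) {
  start <- as.integer(start); end <- as.integer(end)
  anchor <- as.integer(anchor)
  n <- max(length(chrom), length(start))
  chrom <- rep_len(as.character(chrom), n)
  region_type <- rep_len(as.character(region_type), n)
  anchor <- rep_len(anchor, n)
  if (any(end <= start)) {
    stop("validation error: region end <= start at row ",
         which(end <= start)[1])
  }
  if (anyDuplicated(name)) {
    stop("validation error: duplicate region name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  if (!all(region_type %in% region_types)) {
    stop("unknown region_type; must be one of ",
         paste(region_types, collapse = ", "))
  }
  nuc <- region_type %in% c("tss", "pas")
  if (any(nuc & is.na(anchor))) stop("tss/pas regions require an anchor")
  bad <- nuc & !is.na(anchor) & !(start <= anchor & anchor < end)
  if (any(bad)) {
    stop("validation error: anchor outside region at row ", which(bad)[1])
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = as.character(name), region_type = region_type,
             anchor = anchor, stringsAsFactors = FALSE)
}

#' Read a target-region panel from BED
#'
#' Expects at least 4 columns (chrom, start, end, name); optional column 5
#' is the region type and column 6 the anchor coordinate. When the type
#' column is absent every region receives `default_type`, and tss/pas
#' regions default their anchor to the interval midpoint.
#'
#' @param path BED file.
#' @param default_type region type used when column 5 is absent.
#' @return validated region table; see [target_regions()].
#' @export
read_regions <- function(path, default_type = "cpg_marker") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(target_regions(character(), integer(), integer(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop(sprintf("parse error in %s at line %d: expected >= 4 fields",
                 path, which(nf < 4L)[1]))
  }
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
           character(1))
  }
  chrom <- get_col(1)
  start <- as.integer(get_col(2))
  end <- as.integer(get_col(3))
  name <- get_col(4)
  type <- get_col(5)
  type[is.na(type) | !nzchar(type)] <- default_type
  anchor <- suppressWarnings(as.integer(get_col(6)))
  nuc <- type %in% c("tss", "pas")
  anchor[nuc & is.na(anchor)] <-
    ((start + end) %/% 2L)[nuc & is.na(anchor)]
  target_regions(chrom, start, end, name, type, anchor)
}

#' @rdname read_regions
#' @param regions region table to write.
#' @export
write_regions <- function(regions, path) {
  df <- regions[, c("chrom", "start", "end", "name", "region_type", "anchor")]
  df$anchor[is.na(df$anchor)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Split regions into sliding windows
#'
#' Long (2-kb) target regions are decomposed into 1-kb sliding windows with
#' 10-bp steps; each window becomes an independent feature. Windows start at
#' `start`, `start + step`, ... while `start + window <= end`, and are named
#' `<name>:win<k>`.
#'
#' @param regions one or more target regions.
#' @param window window width in bp (must not exceed any region length).
#' @param step step between window starts in bp.
#' @return region table of windows; `parent` column links back to the source
#'   region.
#' @export
make_windows <- function(regions, window = 1000L, step = 10L) {
  if (step < 1L) stop("step must be >= 1")
  lens <- regions$end - regions$start
  if (any(window > lens)) {
    stop("window larger than region length for region ",
         regions$name[which(window > lens)[1]])
  }
  pieces <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    starts <- seq.int(r$start, r$end - window, by = step)
    data.frame(chrom = r$chrom, start = starts, end = starts + window,
               name = sprintf("%s:win%d", r$name, seq_along(starts)),
               region_type = r$region_type, anchor = NA_integer_,
               parent = r$name, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Read a sample sheet
#'
#' Tab-separated with a header row; required columns `sample_id`, `label`,
#' `cohort`, `fragments`, `methylation`; optional `lambda` (spike-in calls).
#'
#' @param path TSV file.
#' @param require_two_classes error unless at least two distinct labels are
#'   present.
#' @export
read_sample_sheet <- function(path, require_two_classes = TRUE) {
  sheet <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  needed <- c("sample_id", "label", "cohort", "fragments", "methylation")
  missing <- setdiff(needed, names(sheet))
  if (length(missing)) {
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  }
  if (require_two_classes && length(unique(sheet$label)) < 2) {
    stop("sample sheet must contain at least two classes")
  }
  sheet
}
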