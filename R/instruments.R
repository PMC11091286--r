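#' LD clumping specification
#'
#' Instruments are pruned so that no two retained SNPs on the same
#' chromosome lie within `window_bp` of each other with pairwise
#' r-squared at or above `r2_threshold`. The defaults (r2 0.001 within
#' 10 Mb) are the conventional strict settings for two-sample MR
#' instrument selection.
#'
#' @param r2_threshold squared LD correlation in \[0, 1\].
#' @param window_bp base-pair window, > 0.
#' @return a list of class `clump_spec`.
#' @export
clump_spec <- function(r2_threshold = 0.001, window_bp = 1e7) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1, window_bp > 0)
  structure(list(r2_threshold = r2_threshold, window_bp = window_bp),
            class = "clump_spec")
}

#' Genome-wide significance filtering
#'
#' Retains records whose association p-value is strictly below the
#' threshold, preserving input order.
#'
#' @param records validated summary-statistic data frame.
#' @param p_threshold significance threshold; default the genome-wide
#'   level 5e-8.
#' @return the retained subset, with a `provenance` attribute recording
#'   before/after counts.
#' @export
select_significant <- function(records, p_threshold = 5e-8) {
  keep <- records$pval < p_threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    filter = "select_significant", p_threshold = p_threshold,
    n_before = nrow(records), n_removed = sum(!keep), n_after = nrow(out)
  )
  out
}

#' Read a pairwise LD table or matrix into an r-squared lookup
#'
#' Accepts either a 3-column table (`snp_a`, `snp_b`, `r2`) or a square
#' matrix with rsIDs as both row and column headers, and returns a
#' function `f(snp_a, snp_b)` giving r-squared (0 when the pair is not
#' listed).
#'
#' @param path TSV file path.
#' @return a lookup function suitable for the `ld` argument of [clump()].
#' @export
read_ld_table <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(first) == 3L && tolower(first[3]) %in% c("r2", "rsq", "r.2")) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    key <- paste(pmin(tab[[1]], tab[[2]]), pmax(tab[[1]], tab[[2]]))
    r2 <- stats::setNames(as.numeric(tab[[3]]), key)
    function(a, b) {
      v <- r2[paste(pmin(a, b), pmax(a, b))]
      ifelse(is.na(v), 0, unname(v))
    }
  } else {
    m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     row.names = 1, check.names = FALSE))
    ld_matrix_lookup(m)
  }
}

#' Wrap a square r-squared matrix as an LD lookup function
#'
#' @param m square numeric matrix with rsID dimnames.
#' @return a function `f(snp_a, snp_b) -> r2` (0 for pairs absent from
#'   the matrix).
#' @export
ld_matrix_lookup <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            !is.null(rownames(m)), !is.null(colnames(m)))
  function(a, b) {
    if (a %in% rownames(m) && b %in% colnames(m)) m[a, b] else 0
  }
}

#' Greedy LD clumping
#'
#' Iterates records by ascending p-value (ties broken by rsID in
#' lexicographic order, so the result is deterministic) and keeps a
#' record unless it lies within `spec$window_bp` of an already-kept
#' record on the same chromosome and either no LD source is supplied
#' (distance-only clumping) or the pairwise r-squared with that kept
#' record is at or above `spec$r2_threshold`.
#'
#' @param records summary statistics with `chrom` and `pos` filled in.
#' @param spec a [clump_spec()].
#' @param ld optional function `(snp_a, snp_b) -> r2`; see
#'   [read_ld_table()]. When `NULL`, proximity alone prunes.
#' @return the retained records in their original input order, with a
#'   `provenance` attribute.
#' @export
clump <- function(records, spec = clump_spec(), ld = NULL) {
  if (nrow(records) == 0L) return(records)
  if (any(is.na(records$pos)) || any(is.na(records$chrom))) {
    stop("clumping requires chromosome and position for every record",
         call. = FALSE)
  }
  ord <- order(records$pval, records$snp_id)
  kept_idx <- integer(0)
  for (i in ord) {
    prune <- FALSE
    for (k in kept_idx) {
      if (records$chrom[i] != records$chrom[k]) next
      if (abs(records$pos[i] - records$pos[k]) > spec$window_bp) next
      if (is.null(ld)) { prune <- TRUE; break }
      r2 <- tryCatch(ld(records$snp_id[i], records$snp_id[k]),
                     error = function(e) {
                       stop("LD lookup failed for pair ",
                            records$snp_id[i], " / ", records$snp_id[k],
                            ": ", conditionMessage(e), call. = FALSE)
                     })
      if (r2 >= spec$r2_threshold) { prune <- TRUE; break }
    }
    if (!prune) kept_idx <- c(kept_idx, i)
  }
  keep <- sort(kept_idx)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    filter = "clump", r2_threshold = spec$r2_threshold,
    window_bp = spec$window_bp, distance_only = is.null(ld),
    n_before = nrow(records), n_removed = nrow(records) - nrow(out),
    n_after = nrow(out)
  )
  out
}

#' Instrument-strength F statistics
#'
#' Computes a per-SNP F statistic by one of two formulas and removes
#' weak instruments. The `ratio` formula is the square of the Wald
#' z-score, `F_j = (beta_j / se_j)^2`, and needs only the effect and its
#' SE. The `r2_based` formula works from the variance in the exposure
#' explained by each SNP, `R2_j = 2 eaf_j (1 - eaf_j) beta_j^2`, with
#' `F_j = R2_j (n - k - 1) / (k (1 - sum(R2)))` for `k` instruments and
#' GWAS sample size `n`; it requires allele frequencies and `n`.
#'
#' @param records summary-statistic data frame.
#' @param n exposure GWAS sample size (required for `r2_based`; when
#'   `NULL`, per-record `n` is used if present).
#' @param formula `"ratio"` (default) or `"r2_based"`.
#' @param f_min weak-instrument threshold; records with `F < f_min` are
#'   removed. Default 10.
#' @return a list with `report` (class `fstat_report`: per-SNP F values,
#'   `min_f`, formula, `n`, `k`) and `records` (the retained subset).
#' @export
f_statistics <- function(records, n = NULL, formula = c("ratio", "r2_based"),
                         f_min = 10) {
  formula <- match.arg(formula)
  k <- nrow(records)
  if (k == 0L) stop("no records supplied", call. = FALSE)
  if (formula == "ratio") {
    f <- (records$beta / records$se)^2
  } else {
    if (is.null(n)) {
      if (all(!is.na(records$n))) n <- max(records$n)
      else stop("r2_based F statistic requires the GWAS sample size n",
                call. = FALSE)
    }
    r2 <- 2 * records$eaf * (1 - records$eaf) * records$beta^2
    if (sum(r2) >= 1) {
      stop("total explained variance >= 1; r2_based approximation invalid",
           call. = FALSE)
    }
    f <- r2 * (n - k - 1) / (k * (1 - sum(r2)))
  }
  report <- structure(
    list(per_snp_f = data.frame(snp_id = records$snp_id, f = f,
                                stringsAsFactors = FALSE),
         min_f = min(f), formula_used = formula,
         n = if (is.null(n)) NA_real_ else n, k = k, f_min = f_min),
    class = "fstat_report"
  )
  keep <- f >= f_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    filter = "f_statistics", formula = formula, f_min = f_min,
    n_before = k, n_removed = sum(!keep), n_after = nrow(out)
  )
  list(report = report, records = out)
}

#' @export
print.fstat_report <- function(x, ...) {
  cat("Instrument strength (", x$formula_used, " formula): k = ", x$k,
      ", min F = ", format(x$min_f, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Parse a blocklist of rsIDs and genomic intervals
#'
#' Each line of the file is either an rsID or a 1-based closed interval
#' `chrom:start-end`.
#'
#' @param path text file path.
#' @return a list with `rsids` (character) and `intervals` (data frame
#'   `chrom`, `start`, `end`).
#' @export
read_blocklist <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  is_iv <- grepl("^[^:]+:[0-9]+-[0-9]+$", lines)
  ivs <- lines[is_iv]
  intervals <- if (length(ivs)) {
    m <- regmatches(ivs, regexec("^([^:]+):([0-9]+)-([0-9]+)$", ivs))
    data.frame(chrom = vapply(m, `[`, "", 2),
               start = as.numeric(vapply(m, `[`, "", 3)),
               end = as.numeric(vapply(m, `[`, "", 4)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  list(rsids = lines[!is_iv], intervals = intervals)
}

#' Exclude instruments overlapping known outcome-risk loci
#'
#' Removes records matching a blocklisted rsID or falling inside any
#' blocklisted 1-based closed interval, e.g. loci with established
#' direct effects on the outcome that would violate the exclusion
#' restriction.
#'
#' @param records summary-statistic data frame.
#' @param blocklist either a list as returned by [read_blocklist()], a
#'   character vector of rsIDs, or a data frame of intervals
#'   (`chrom`, `start`, `end`).
#' @return the retained records with a `provenance` attribute.
#' @export
exclude_blocklist <- function(records, blocklist) {
  if (is.character(blocklist)) {
    blocklist <- list(rsids = blocklist,
                      intervals = data.frame(chrom = character(0),
                                             start = numeric(0),
                                             end = numeric(0)))
  } else if (is.data.frame(blocklist)) {
    blocklist <- list(rsids = character(0), intervals = blocklist)
  }
  iv <- blocklist$intervals
  if (nrow(iv) && any(iv$start > iv$end)) {
    stop("malformed blocklist interval: start > end", call. = FALSE)
  }
  hit <- records$snp_id %in% blocklist$rsids
  if (nrow(iv)) {
    for (r in seq_len(nrow(iv))) {
      hit <- hit | (records$chrom == iv$chrom[r] &
                      !is.na(records$pos) &
                      records$pos >= iv$start[r] &
                      records$pos <= iv$end[r])
    }
  }
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    filter = "exclude_blocklist",
    n_before = nrow(records), n_removed = sum(hit), n_after = nrow(out)
  )
  out
}

#' Run the full instrument-selection cascade
#'
#' Applies, in order: genome-wide significance filtering, LD clumping,
#' blocklist exclusion and F-statistic screening, accumulating
#' before/after counts for every stage.
#'
#' @param records exposure summary statistics.
#' @param p_threshold significance threshold (default 5e-8).
#' @param spec a [clump_spec()].
#' @param ld optional LD lookup for [clump()].
#' @param blocklist optional blocklist for [exclude_blocklist()].
#' @param n exposure sample size for the `r2_based` F formula.
#' @param f_formula F-statistic formula, `"ratio"` or `"r2_based"`.
#' @param f_min weak-instrument threshold.
#' @return list with `records` (selected instruments), `fstat_report`,
#'   and `provenance` (list of per-stage count records).
#' @export
select_instruments <- function(records, p_threshold = 5e-8,
                               spec = clump_spec(), ld = NULL,
                               blocklist = NULL, n = NULL,
                               f_formula = "ratio", f_min = 10) {
  prov <- list()
  out <- select_significant(records, p_threshold)
  prov$significance <- attr(out, "provenance")
  if (nrow(out) == 0L) {
    return(list(records = out, fstat_report = NULL, provenance = prov))
  }
  out <- clump(out, spec, ld)
  prov$clump <- attr(out, "provenance")
  if (!is.null(blocklist)) {
    out <- exclude_blocklist(out, blocklist)
    prov$blocklist <- attr(out, "provenance")
  }
  fs <- f_statistics(out, n = n, formula = f_formula, f_min = f_min)
  prov$fstat <- attr(fs$records, "provenance")
  list(records = fs$records, fstat_report = fs$report, provenance = prov)
}
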