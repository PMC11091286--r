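#' Column dialects for summary-statistic files
#'
#' A dialect maps the canonical field names used throughout the package
#' (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`) to the column headers of a particular file
#' layout. Presets are provided for the instrument-table layout used by
#' this package's fixtures (`"default"`), GWAS Catalog harmonized exports
#' (`"gwas-catalog"`) and IEU OpenGWAS flat exports (`"ieu-opengwas"`).
#'
#' @param preset name of a built-in dialect, or `NULL` to build one from
#'   the `...` arguments alone.
#' @param ... named overrides, e.g. `snp_id = "MarkerName"`. The `n`
#'   mapping is optional; all other canonical fields must resolve.
#' @return a named character vector mapping canonical names to file
#'   column names, of class `"sumstats_dialect"`.
#' @export
#' @examples
#' sumstats_dialect("gwas-catalog")
#' sumstats_dialect("default", pval = "P")
sumstats_dialect <- function(preset = "default", ...) {
  presets <- list(
    "default" = c(
      snp_id = "SNP", chrom = "Chr", pos = "Pos",
      effect_allele = "Effect allele", other_allele = "Other allele",
      eaf = "Eaf", beta = "Beta", se = "Se", pval = "Pval", n = "N"
    ),
    "gwas-catalog" = c(
      snp_id = "variant_id", chrom = "chromosome", pos = "base_pair_location",
      effect_allele = "effect_allele", other_allele = "other_allele",
      eaf = "effect_allele_frequency", beta = "beta", se = "standard_error",
      pval = "p_value", n = "n"
    ),
    "ieu-opengwas" = c(
      snp_id = "SNP", chrom = "chr", pos = "position",
      effect_allele = "ea", other_allele = "nea",
      eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "samplesize"
    )
  )
  base <- if (is.null(preset)) {
    c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
      effect_allele = "effect_allele", other_allele = "other_allele",
      eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n")
  } else {
    if (!preset %in% names(presets)) {
      stop("unknown dialect preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    presets[[preset]]
  }
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad)) {
      stop("unknown canonical field(s) in dialect: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    base[names(dots)] <- dots
  }
  structure(base, class = "sumstats_dialect")
}

canonical_fields <- function() {
  c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pval")
}

#' Read and validate GWAS summary statistics
#'
#' Reads a delimited text file (tab or comma separated, optionally
#' gzip-compressed) of per-SNP association summaries and returns a
#' validated data frame with canonical column names. Positions are
#' 1-based. Rows violating the record invariants (alleles must be single
#' distinct A/C/G/T bases, `0 < eaf < 1`, `se > 0`, `0 < pval <= 1`,
#' finite `beta`) are dropped with row-numbered diagnostics unless
#' `strict = TRUE`, in which case the first violation is fatal.
#'
#' @param path file path; `.gz` files are read transparently.
#' @param dialect a [sumstats_dialect()] or the name of a preset.
#' @param sep field separator; `NULL` (default) autodetects tab vs comma
#'   from the header line.
#' @param strict logical; make row-level validation failures fatal.
#' @return a `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval` and
#'   `n` (`NA` when the file has no sample-size column). The number of
#'   rejected rows is recorded in `attr(, "n_rejected")` and the
#'   per-row messages in `attr(, "rejections")`.
#' @export
read_sumstats <- function(path, dialect = "default", sep = NULL,
                          strict = FALSE) {
  if (is.character(dialect) && length(dialect) == 1L) {
    dialect <- sumstats_dialect(dialect)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("empty summary-statistics file: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\t", lines[1])) "\t" else ","
  }
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (length(lines) > 1L) {
    raw <- utils::read.table(text = lines[-1], header = FALSE, sep = sep,
                             colClasses = "character", quote = "\"",
                             comment.char = "", fill = TRUE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) != length(header)) {
      stop("header has ", length(header), " columns but data rows have ",
           ncol(raw), call. = FALSE)
    }
    names(raw) <- header
  } else {
    raw <- as.data.frame(matrix(character(0), nrow = 0,
                                ncol = length(header),
                                dimnames = list(NULL, header)),
                         stringsAsFactors = FALSE)
  }

  needed <- canonical_fields()
  missing_cols <- needed[!dialect[needed] %in% header]
  if (length(missing_cols)) {
    stop("dialect maps field(s) ", paste(missing_cols, collapse = ", "),
         " to column(s) ", paste(dialect[missing_cols], collapse = ", "),
         " absent from the file header", call. = FALSE)
  }
  has_n <- !is.na(dialect["n"]) && dialect[["n"]] %in% header

  if (nrow(raw) == 0L) {
    warning("no data rows in ", path, call. = FALSE)
    out <- empty_sumstats()
    attr(out, "n_rejected") <- 0L
    attr(out, "rejections") <- character(0)
    return(out)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    snp_id = as.character(raw[[dialect[["snp_id"]]]]),
    chrom = as.character(raw[[dialect[["chrom"]]]]),
    pos = num(raw[[dialect[["pos"]]]]),
    effect_allele = toupper(trimws(raw[[dialect[["effect_allele"]]]])),
    other_allele = toupper(trimws(raw[[dialect[["other_allele"]]]])),
    eaf = num(raw[[dialect[["eaf"]]]]),
    beta = num(raw[[dialect[["beta"]]]]),
    se = num(raw[[dialect[["se"]]]]),
    pval = num(raw[[dialect[["pval"]]]]),
    n = if (has_n) num(raw[[dialect[["n"]]]]) else NA_real_,
    stringsAsFactors = FALSE
  )
  validate_sumstats(out, strict = strict, source = path)
}

empty_sumstats <- function() {
  data.frame(snp_id = character(0), chrom = character(0), pos = numeric(0),
             effect_allele = character(0), other_allele = character(0),
             eaf = numeric(0), beta = numeric(0), se = numeric(0),
             pval = numeric(0), n = numeric(0), stringsAsFactors = FALSE)
}

#' Validate a summary-statistics data frame
#'
#' Applies the per-record invariants to a data frame already in canonical
#' form. Offending rows are removed (or fatal under `strict = TRUE`).
#'
#' @param x data.frame with the canonical columns (see [read_sumstats()]).
#' @param strict logical; fail on the first invalid row.
#' @param source label used in diagnostics.
#' @return the validated subset, with attributes `n_rejected` and
#'   `rejections` (character vector of row-numbered messages).
#' @export
validate_sumstats <- function(x, strict = FALSE, source = "sumstats") {
  needed <- c(canonical_fields(), "n")
  miss <- setdiff(canonical_fields(), names(x))
  if (length(miss)) {
    stop("missing canonical column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"n" %in% names(x)) x$n <- NA_real_
  x <- x[, needed]
  bases <- c("A", "C", "G", "T")
  problems <- character(nrow(x))
  bad <- logical(nrow(x))
  flag <- function(cond, msg) {
    hit <- cond & !bad
    problems[hit] <<- msg
    bad <<- bad | cond
  }
  flag(is.na(x$snp_id) | !nzchar(x$snp_id), "missing snp_id")
  flag(!x$effect_allele %in% bases | !x$other_allele %in% bases,
       "alleles must be single A/C/G/T bases")
  flag(!is.na(x$effect_allele) & x$effect_allele == x$other_allele,
       "effect and other allele identical")
  flag(is.na(x$eaf) | x$eaf <= 0 | x$eaf >= 1, "eaf outside (0, 1)")
  flag(is.na(x$beta) | !is.finite(x$beta), "beta not a finite number")
  flag(is.na(x$se) | x$se <= 0, "se must be > 0")
  flag(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "pval outside (0, 1]")
  flag(!is.na(x$n) & x$n <= 0, "n must be positive")

  if (any(bad)) {
    msgs <- sprintf("%s row %d (%s): %s", source, which(bad),
                    ifelse(is.na(x$snp_id[bad]), "?", x$snp_id[bad]),
                    problems[bad])
    if (strict) stop(msgs[1], call. = FALSE)
    warning(sum(bad), " row(s) rejected while reading ", source,
            call. = FALSE)
  } else {
    msgs <- character(0)
  }
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "rejections") <- msgs
  out
}

complement_bases <- function(x) chartr("ACGT", "TGCA", x)

is_palindromic <- function(a1, a2) a1 == complement_bases(a2)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns exposure and outcome effects to a common effect allele per SNP,
#' joining on rsID. Outcome records whose alleles are listed in the
#' opposite order have their beta negated and eaf replaced by `1 - eaf`
#' (`action = "flipped"`). When `strand_flip = TRUE` (default), outcome
#' alleles reported on the opposite strand are complemented before
#' comparison. Palindromic SNPs (A/T or C/G) carry no strand information
#' and are resolved from allele frequency: they are kept only when both
#' studies' frequencies fall on the same side of 0.5 and both minor-allele
#' frequencies are below `palindrome_eaf_limit`; otherwise they are
#' dropped as ambiguous. Allele sets that cannot be reconciled are
#' dropped as incompatible.
#'
#' @param exposure,outcome validated summary-statistic data frames
#'   (see [read_sumstats()]); join key is `snp_id`.
#' @param palindrome_eaf_limit MAF ceiling below which a same-side
#'   palindromic SNP is considered unambiguous. Default 0.42.
#' @param strand_flip attempt strand-complement reconciliation for
#'   non-palindromic allele mismatches.
#' @param exposure_label,outcome_label trait labels carried into reports.
#' @return an object of class `harmonized_set`: a list with elements
#'   `pairs` (data frame, one row per overlapping SNP, with exposure and
#'   outcome effects and an `action` column taking values `kept`,
#'   `flipped`, `dropped_palindromic` or `dropped_incompatible`; dropped
#'   rows carry `NA` outcome effects), `exposure_label`, `outcome_label`
#'   and `provenance` (filter counts).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42,
                      strand_flip = TRUE,
                      exposure_label = "exposure",
                      outcome_label = "outcome") {
  if (anyDuplicated(exposure$snp_id)) {
    stop("duplicate snp_id in exposure summary statistics", call. = FALSE)
  }
  if (anyDuplicated(outcome$snp_id)) {
    stop("duplicate snp_id in outcome summary statistics", call. = FALSE)
  }
  common <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(common) == 0L) stop("no overlapping instruments", call. = FALSE)
  ex <- exposure[match(common, exposure$snp_id), ]
  ou <- outcome[match(common, outcome$snp_id), ]

  n <- length(common)
  action <- character(n)
  o_beta <- o_se <- o_eaf <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)

    orient <- NA_character_  # "same" or "swap"
    if (ea_y == ea_x && oa_y == oa_x) {
      orient <- "same"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      orient <- "swap"
    } else if (!pal && strand_flip) {
      cy <- complement_bases(ea_y); cz <- complement_bases(oa_y)
      if (cy == ea_x && cz == oa_x) orient <- "same"
      else if (cy == oa_x && cz == ea_x) orient <- "swap"
    }

    if (is.na(orient)) {
      action[i] <- "dropped_incompatible"
      next
    }
    eaf_y <- if (orient == "same") ou$eaf[i] else 1 - ou$eaf[i]
    if (pal) {
      same_side <- (ex$eaf[i] - 0.5) * (eaf_y - 0.5) > 0
      maf_ok <- min(ex$eaf[i], 1 - ex$eaf[i]) < palindrome_eaf_limit &&
        min(eaf_y, 1 - eaf_y) < palindrome_eaf_limit
      if (!(same_side && maf_ok)) {
        action[i] <- "dropped_palindromic"
        next
      }
    }
    action[i] <- if (orient == "same") "kept" else "flipped"
    o_beta[i] <- if (orient == "same") ou$beta[i] else -ou$beta[i]
    o_se[i] <- ou$se[i]
    o_eaf[i] <- eaf_y
  }

  pairs <- data.frame(
    snp_id = common,
    chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    exposure_beta = ex$beta, exposure_se = ex$se, exposure_eaf = ex$eaf,
    outcome_beta = o_beta, outcome_se = o_se, outcome_eaf = o_eaf,
    action = action, stringsAsFactors = FALSE
  )
  prov <- list(
    n_exposure = nrow(exposure), n_outcome = nrow(outcome),
    n_overlap = n,
    n_kept = sum(action %in% c("kept", "flipped")),
    n_flipped = sum(action == "flipped"),
    n_dropped_palindromic = sum(action == "dropped_palindromic"),
    n_dropped_incompatible = sum(action == "dropped_incompatible"),
    palindrome_eaf_limit = palindrome_eaf_limit,
    strand_flip = strand_flip
  )
  new_harmonized_set(pairs, exposure_label, outcome_label, prov)
}

new_harmonized_set <- function(pairs, exposure_label, outcome_label,
                               provenance = list()) {
  stopifnot(is.data.frame(pairs))
  structure(
    list(pairs = pairs, exposure_label = exposure_label,
         outcome_label = outcome_label, provenance = provenance),
    class = "harmonized_set"
  )
}

#' Construct a harmonized instrument set from aligned effect vectors
#'
#' Convenience constructor for effects already aligned to a common effect
#' allele (e.g. simulated data, or worked examples). All vectors are
#' recycled to the length of `exposure_beta`.
#'
#' @param snp_id instrument identifiers; defaults to `snp_1 ... snp_J`.
#' @param exposure_beta,exposure_se SNP-exposure effects and SEs.
#' @param outcome_beta,outcome_se SNP-outcome effects and SEs.
#' @param exposure_eaf,outcome_eaf optional effect-allele frequencies.
#' @param exposure_label,outcome_label trait labels.
#' @return a `harmonized_set` whose pairs all have `action = "kept"`.
#' @export
harmonized_set <- function(exposure_beta, exposure_se,
                           outcome_beta, outcome_se,
                           snp_id = NULL,
                           exposure_eaf = NA_real_, outcome_eaf = NA_real_,
                           exposure_label = "exposure",
                           outcome_label = "outcome") {
  j <- length(exposure_beta)
  if (is.null(snp_id)) snp_id <- paste0("snp_", seq_len(j))
  stopifnot(length(outcome_beta) == j, !anyDuplicated(snp_id))
  exposure_se <- rep_len(exposure_se, j)
  outcome_se <- rep_len(outcome_se, j)
  pairs <- data.frame(
    snp_id = snp_id, chrom = NA_character_, pos = NA_real_,
    effect_allele = NA_character_, other_allele = NA_character_,
    exposure_beta = exposure_beta, exposure_se = exposure_se,
    exposure_eaf = rep_len(exposure_eaf, j),
    outcome_beta = outcome_beta, outcome_se = outcome_se,
    outcome_eaf = rep_len(outcome_eaf, j),
    action = "kept", stringsAsFactors = FALSE
  )
  new_harmonized_set(pairs, exposure_label, outcome_label,
                     list(n_kept = j))
}

#' Retained pairs of a harmonized set
#'
#' @param set a `harmonized_set`.
#' @return the subset of `set$pairs` with `action` `kept` or `flipped`.
#' @export
kept_pairs <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  out <- set$pairs[set$pairs$action %in% c("kept", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized instrument set:", x$exposure_label, "->",
      x$outcome_label, "\n")
  tab <- table(x$pairs$action)
  cat("  SNPs:", nrow(x$pairs), "(",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Write a harmonized set to TSV
#'
#' One row per overlapping SNP, including the `action` column, so the
#' disposition of every instrument is auditable.
#'
#' @param set a `harmonized_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(set, path) {
  stopifnot(inherits(set, "harmonized_set"))
  utils::write.table(set$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Two-sided normal p-value from an effect and its standard error
#'
#' Computes `2 * pnorm(-|beta/se|)` on the log scale internally, so
#' extremely small p-values (below 1e-300) remain representable instead
#' of underflowing at intermediate steps.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), all > 0.
#' @param log10 if `TRUE`, return `log10(p)` instead of `p` (useful when
#'   even the final value would underflow).
#' @return p-values in (0, 1], or their base-10 logs.
#' @export
#' @examples
#' pval_from_effect(1.959964, 1)   # ~0.05
#' pval_from_effect(0.242, 0.043)  # genome-wide significant
pval_from_effect <- function(beta, se, log10 = FALSE) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  logp <- stats::pnorm(-abs(beta / se), log.p = TRUE) + log(2)
  if (log10) logp / log(10) else exp(logp)
}
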