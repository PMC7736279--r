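#' Delta-Ct relative quantification
#'
#' Averages replicate Ct values per sample/assay, computes
#' `dCt = mean Ct(target) - mean Ct(reference)` and the relative quantity
#' `2^(-dCt)`. Undetermined Ct values (NA, or the strings "undetermined" /
#' "Undetermined") are excluded from replicate averaging; an assay with no
#' determined replicate is flagged absent (NA), not zero-imputed. Samples
#' whose reference assay is undetermined are excluded with a warning.
#'
#' @param ct data.frame with columns `sample_id`, `assay`, `replicate`,
#'   `ct` (numeric or character; optionally a `group` column carried
#'   through).
#' @param reference_assay reference gene assay, e.g. `"ACTB"` or `"TOP1"`.
#' @param undetermined `"exclude"` (default) or `"max_cycle"` to impute
#'   undetermined values at `max_cycle`.
#' @param max_cycle cycle count used when `undetermined = "max_cycle"`.
#' @return object of class `cf_qpcr`: list with `quantities` (wide
#'   data.frame sample x assay of relative quantities), `delta_ct` (wide
#'   dCt), `mean_ct`, `groups`, `excluded`.
#' @export
delta_ct <- function(ct, reference_assay,
                     undetermined = c("exclude", "max_cycle"),
                     max_cycle = 40) {
  undetermined <- match.arg(undetermined)
  req <- c("sample_id", "assay", "replicate", "ct")
  if (!all(req %in% names(ct)))
    stop("ct table must have columns: ", paste(req, collapse = ", "))
  vals <- ct$ct
  if (!is.numeric(vals)) {
    und <- tolower(trimws(as.character(vals))) == "undetermined"
    vals <- suppressWarnings(as.numeric(as.character(vals)))
    vals[und] <- NA_real_
  }
  if (any(vals <= 0, na.rm = TRUE)) stop("determined Ct values must be > 0")
  if (undetermined == "max_cycle") vals[is.na(vals)] <- max_cycle
  ct$.ct <- vals

  mean_ct <- stats::aggregate(.ct ~ sample_id + assay, data = ct,
                              FUN = mean, na.action = stats::na.pass,
                              na.rm = TRUE)
  mean_ct$.ct[is.nan(mean_ct$.ct)] <- NA_real_
  wide <- stats::reshape(mean_ct, idvar = "sample_id", timevar = "assay",
                         direction = "wide")
  names(wide) <- sub("^\\.ct\\.", "", names(wide))
  rownames(wide) <- wide$sample_id
  if (!reference_assay %in% names(wide))
    stop("reference assay '", reference_assay, "' not in ct table")

  ref <- wide[[reference_assay]]
  bad <- is.na(ref)
  excluded_ids <- wide$sample_id[bad]
  if (any(bad)) {
    warning("reference assay undetermined; excluding sample(s): ",
            paste(excluded_ids, collapse = ", "))
    wide <- wide[!bad, , drop = FALSE]
    ref <- ref[!bad]
  }
  assays <- setdiff(names(wide), "sample_id")
  dct <- wide
  q <- wide
  for (a in assays) {
    dct[[a]] <- wide[[a]] - ref
    q[[a]] <- 2^(-dct[[a]])
  }
  groups <- NULL
  if ("group" %in% names(ct)) {
    gmap <- unique(ct[, c("sample_id", "group")])
    groups <- stats::setNames(gmap$group, gmap$sample_id)[wide$sample_id]
  }
  structure(list(quantities = q, delta_ct = dct, mean_ct = wide,
                 reference_assay = reference_assay, groups = groups,
                 excluded = excluded_ids),
            class = "cf_qpcr")
}

#' Marker ratios: NRIP1/ZEB2 and linear/circular NRIP1
#'
#' Computes, per sample, the ratio of relative quantities of the target
#' over the denominator assay (default NRIP1_linear / ZEB2) and of the
#' linear over the circular target form (NRIP1_linear / NRIP1_circ), and
#' compares each affected group against the control group with a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test. Ratios with an absent
#' denominator are flagged absent (NA). Groups with fewer than 2 samples
#' are skipped with a warning.
#'
#' @param q `cf_qpcr` from [delta_ct()] (must carry group labels).
#' @param target,denom,circular assay names.
#' @param control_group label of the control group (default `"control"`).
#' @return list with `ratios` (per-sample data.frame) and `tests`
#'   (per-group data.frame of Mann-Whitney p-values for both ratios).
#' @export
marker_ratios <- function(q, target = "NRIP1_linear", denom = "ZEB2",
                          circular = "NRIP1_circ",
                          control_group = "control") {
  qt <- q$quantities
  if (is.null(q$groups)) stop("group labels required (generate the ct table with a group column)")
  get <- function(a) if (a %in% names(qt)) qt[[a]] else rep(NA_real_, nrow(qt))
  ratio <- get(target) / get(denom)
  lin_circ <- get(target) / get(circular)
  ratio[!is.finite(ratio)] <- NA_real_
  lin_circ[!is.finite(lin_circ)] <- NA_real_
  ratios <- data.frame(sample_id = qt$sample_id, group = unname(q$groups),
                       target_ratio = ratio, lin_circ_ratio = lin_circ,
                       stringsAsFactors = FALSE)

  grps <- setdiff(unique(ratios$group), control_group)
  tests <- list()
  for (g in grps) {
    row <- data.frame(group = g, p_target_ratio = NA_real_,
                      p_lin_circ = NA_real_, stringsAsFactors = FALSE)
    a <- ratios[ratios$group == g, ]
    b <- ratios[ratios$group == control_group, ]
    if (nrow(a) < 2 || nrow(b) < 2) {
      warning("group '", g, "' or control has < 2 samples; test skipped")
    } else {
      if (sum(!is.na(a$target_ratio)) >= 2 && sum(!is.na(b$target_ratio)) >= 2)
        row$p_target_ratio <- stats::wilcox.test(
          a$target_ratio, b$target_ratio, exact = FALSE)$p.value
      if (sum(!is.na(a$lin_circ_ratio)) >= 2 && sum(!is.na(b$lin_circ_ratio)) >= 2)
        row$p_lin_circ <- stats::wilcox.test(
          a$lin_circ_ratio, b$lin_circ_ratio, exact = FALSE)$p.value
    }
    tests[[g]] <- row
  }
  list(ratios = ratios,
       tests = if (length(tests)) do.call(rbind, c(tests, make.row.names = FALSE))
               else data.frame(group = character(), p_target_ratio = numeric(),
                               p_lin_circ = numeric()))
}

#' Pregnancy-marker positivity test (VGLL3-style)
#'
#' Positivity is a determined Ct below `ct_cutoff` for the marker assay;
#' pregnant and non-pregnant positivity counts are compared with Fisher's
#' exact test.
#'
#' @param ct raw ct table (long format, with `group`).
#' @param marker assay name (default `"VGLL3"`).
#' @param ct_cutoff positivity cutoff in cycles (default 40).
#' @param pregnant_groups group labels counted as pregnant; all other
#'   groups count as non-pregnant.
#' @return list with `per_sample` (sample, group, positive), `table`
#'   (2x2 contingency), `p_value` (Fisher's exact, two-sided).
#' @export
detect_pregnancy_marker <- function(ct, marker = "VGLL3", ct_cutoff = 40,
                                    pregnant_groups = c("pregnant",
                                                        "normal_pregnant")) {
  sub <- ct[ct$assay == marker, , drop = FALSE]
  if (nrow(sub) == 0) stop("marker assay '", marker, "' not in ct table")
  vals <- sub$ct
  if (!is.numeric(vals)) {
    und <- tolower(trimws(as.character(vals))) == "undetermined"
    vals <- suppressWarnings(as.numeric(as.character(vals)))
    vals[und] <- NA_real_
  }
  sub$.ct <- vals
  agg <- stats::aggregate(.ct ~ sample_id + group, data = sub, FUN = mean,
                          na.action = stats::na.pass, na.rm = TRUE)
  positive <- !is.na(agg$.ct) & !is.nan(agg$.ct) & agg$.ct < ct_cutoff
  pregnant <- agg$group %in% pregnant_groups
  tab <- table(factor(pregnant, c(TRUE, FALSE), c("pregnant", "non_pregnant")),
               factor(positive, c(TRUE, FALSE), c("positive", "negative")))
  p <- stats::fisher.test(tab)$p.value
  list(per_sample = data.frame(sample_id = agg$sample_id, group = agg$group,
                               positive = positive, stringsAsFactors = FALSE),
       table = tab, p_value = p)
}
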