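#' Relative expression by the 2^-ddCt method with dual reference genes
#'
#' Technical replicates are averaged first. For each biological replicate,
#' `dCt = mean Ct(target) - mean(mean Ct(ref1), mean Ct(ref2))`; `ddCt`
#' subtracts the mean `dCt` of the calibrator zeitgeber-time group, and
#' the fold change is `2^-ddCt` (amplification efficiency fixed at 2, the
#' assumption of the method). The arithmetic mean of the two reference-gene
#' Cts is equivalent to normalising by the geometric mean of their
#' expression levels. Fold changes are invariant to any constant added to
#' all Ct values, and the calibrator group's mean dCt maps to fold 1 by
#' construction.
#'
#' @param records data.frame with columns `gene`, `zt`,
#'   `biological_replicate`, `technical_replicate`, `ct` (cycles, finite
#'   and positive).
#' @param target target gene name.
#' @param references character vector of reference genes (default
#'   `c("RPS13", "G3PDH")`).
#' @param calibrator_zt zeitgeber-time label of the calibrator group
#'   (default `"ZT1"`).
#' @return data.frame (`relative_expression`): `gene`, `zt`,
#'   `biological_replicate`, `dct`, `ddct`, `fold_change`, `calibrator`.
#'   Biological replicates missing a reference Ct are excluded with a
#'   message.
#' @export
compute_relative_expression <- function(records, target,
                                        references = c("RPS13", "G3PDH"),
                                        calibrator_zt = "ZT1") {
  stopifnot(all(c("gene", "zt", "biological_replicate", "ct")
                %in% names(records)))
  if (any(!is.finite(records$ct)) || any(records$ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  if (!target %in% records$gene) stop("target gene not found: ", target)
  miss_ref <- setdiff(references, records$gene)
  if (length(miss_ref)) {
    stop("reference gene(s) not found: ", paste(miss_ref, collapse = ", "))
  }
  # technical means per (gene, zt, bio)
  tm <- stats::aggregate(ct ~ gene + zt + biological_replicate,
                         data = records, FUN = mean)
  rows <- list()
  for (z in unique(tm$zt)) {
    for (b in unique(tm$biological_replicate[tm$zt == z])) {
      sel <- tm$zt == z & tm$biological_replicate == b
      tgt <- tm$ct[sel & tm$gene == target]
      refs <- vapply(references, function(r) {
        v <- tm$ct[sel & tm$gene == r]
        if (length(v)) v else NA_real_
      }, numeric(1))
      if (!length(tgt) || any(is.na(refs))) {
        message("excluding biological replicate ", b, " at ", z,
                ": missing target or reference Ct")
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene = target, zt = z, biological_replicate = b,
        dct = tgt - mean(refs))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !calibrator_zt %in% out$zt) {
    stop("calibrator group '", calibrator_zt, "' has no usable replicates")
  }
  cal <- mean(out$dct[out$zt == calibrator_zt])
  out$ddct <- out$dct - cal
  out$fold_change <- 2^(-out$ddct)
  out$calibrator <- calibrator_zt
  class(out) <- c("relative_expression", class(out))
  out
}

#' Compare relative expression across zeitgeber times
#'
#' Per-biological-replicate fold changes are compared across ZT groups
#' with the standard decision tree ([run_group_comparison()]): one-way
#' ANOVA with Tukey post hoc when normality and equal variance hold
#' (after log transform if needed), otherwise ANOVA on ranks with Dunn's
#' test.
#'
#' @param expr a `relative_expression` table from
#'   [compute_relative_expression()].
#' @param alpha significance level.
#' @return a `group_test`.
#' @export
compare_expression_across_zt <- function(expr, alpha = 0.05) {
  stopifnot(all(c("zt", "fold_change") %in% names(expr)))
  run_group_comparison(split(expr$fold_change, expr$zt), alpha = alpha)
}
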