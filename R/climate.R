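#' Prune collinear environmental layers
#'
#' Walks the layer pairs in input order and, whenever two retained layers
#' correlate with `|r| > r_max`, drops the later-listed layer — so input
#' order encodes user priority over which of a collinear pair survives.
#' Constant layers are excluded from the correlation test and retained,
#' with a message.
#'
#' @param env Numeric matrix, cells x layers, with column names.
#' @param r_max Pairwise correlation threshold (default 0.85; pairs with
#'   `|r|` strictly above are collinear).
#' @return Character vector of retained layer names, in input order.
#' @export
prune_variables <- function(env, r_max = 0.85) {
  if (ncol(env) < 2) abort("need at least two layers to prune")
  nm <- colnames(env)
  if (is.null(nm)) nm <- colnames(env) <- paste0("env", seq_len(ncol(env)))
  constant <- apply(env, 2, function(v) stats::sd(v) == 0)
  if (any(constant))
    message(sprintf("prune_variables: %d constant layer(s) retained without testing",
                    sum(constant)))
  keep <- rep(TRUE, ncol(env))
  idx <- which(!constant)
  if (length(idx) >= 2) {
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      i <- idx[a]; j <- idx[b]
      if (!keep[i] || !keep[j]) next
      if (abs(stats::cor(env[, i], env[, j])) > r_max) keep[j] <- FALSE
    }
  }
  nm[keep]
}

#' Species eligible for suitability modelling
#'
#' Species with fewer than `min_records` occurrence records are excluded
#' (distribution models are unreliable below that size); the number
#' excluded is reported in a message.
#'
#' @param counts Named integer vector of occurrence-record counts per
#'   species.
#' @param min_records Minimum record count (default 5; a species with
#'   exactly 5 records is retained).
#' @return Character vector of retained species ids.
#' @export
eligible_species <- function(counts, min_records = 5) {
  keep <- counts >= min_records
  message(sprintf("eligible_species: excluded %d of %d species with < %d records",
                  sum(!keep), length(counts), min_records))
  names(counts)[keep]
}

#' Filter species by model AUC
#'
#' Species whose model AUC is below `auc_min` (strictly) are excluded;
#' species with a missing AUC are excluded with a warning.
#'
#' @param auc_table Data.frame with columns `species_id` and `auc`.
#' @param auc_min Minimum AUC (default 0.7; exactly 0.7 is retained).
#' @return Character vector of retained species ids.
#' @export
auc_filter <- function(auc_table, auc_min = 0.7) {
  miss <- is.na(auc_table$auc)
  if (any(miss))
    warning(sprintf("auc_filter: %d species with missing AUC excluded", sum(miss)))
  as.character(auc_table$species_id[!miss & auc_table$auc >= auc_min])
}

#' Binarize a suitability stack into presence/absence ranges
#'
#' A species is taken to occur in a cell iff its suitability there is
#' strictly greater than `s_min` (a value of exactly `s_min` is absence).
#'
#' @param stack Numeric matrix, cells x species, values in \[0, 1\].
#' @param s_min Suitability threshold (default 0.6).
#' @return Logical matrix of the same shape.
#' @export
binary_range <- function(stack, s_min = 0.6) {
  if (any(stack < 0 | stack > 1)) abort("suitability values must lie in [0, 1]")
  stack > s_min
}

#' Richness and richness-change surfaces between two scenarios
#'
#' @param cur,fut Logical cells x species range matrices (same shape, same
#'   species columns) from [binary_range()].
#' @return A data.frame with one row per cell and columns `richness_cur`,
#'   `richness_fut`, `gain` (species absent now, present later), `loss`
#'   (present now, absent later) and `net` (= fut - cur = gain - loss).
#' @export
richness_and_change <- function(cur, fut) {
  if (!identical(dim(cur), dim(fut)) || !identical(colnames(cur), colnames(fut)))
    abort("scenario stacks must share grid and species set")
  gain <- rowSums(fut & !cur)
  loss <- rowSums(cur & !fut)
  data.frame(cell = seq_len(nrow(cur)),
             richness_cur = as.integer(rowSums(cur)),
             richness_fut = as.integer(rowSums(fut)),
             gain = as.integer(gain), loss = as.integer(loss),
             net = as.integer(gain - loss))
}

#' Per-species habitat change between two scenarios
#'
#' For each species, compares the current and future binary ranges:
#' `lsa` (loss of suitable area) is the fraction of current-range cells
#' that fall out of the range in the future; `shift` is (cells gained +
#' cells lost) / current range size; the change class is contraction,
#' no_change or expansion by the sign of the area change. A species with
#' an empty current range cannot be assessed (`assessable = FALSE`).
#'
#' @inheritParams richness_and_change
#' @return A data.frame with columns `species_id`, `a_cur`, `a_fut`,
#'   `n_lost`, `n_gained`, `change`, `lsa`, `shift`, `assessable`.
#' @export
habitat_change <- function(cur, fut) {
  if (!identical(dim(cur), dim(fut)) || !identical(colnames(cur), colnames(fut)))
    abort("scenario stacks must share grid and species set")
  a_cur <- colSums(cur)
  a_fut <- colSums(fut)
  n_lost <- colSums(cur & !fut)
  n_gained <- colSums(!cur & fut)
  assessable <- a_cur > 0
  lsa <- ifelse(assessable, n_lost / a_cur, NA_real_)
  shift <- ifelse(assessable, (n_lost + n_gained) / a_cur, NA_real_)
  change <- ifelse(a_fut < a_cur, "contraction",
                   ifelse(a_fut > a_cur, "expansion", "no_change"))
  change[!assessable] <- NA_character_
  data.frame(species_id = colnames(cur),
             a_cur = as.integer(a_cur), a_fut = as.integer(a_fut),
             n_lost = as.integer(n_lost), n_gained = as.integer(n_gained),
             change = change, lsa = lsa, shift = shift,
             assessable = assessable, row.names = NULL)
}

#' Reclassify threat category from loss of suitable area
#'
#' Half-open LSA bands: EX at exactly 100% loss, CR \[80, 100)%, EN
#' \[50, 80)%, VU \[30, 50)%, CC below 30%.
#'
#' @param lsa Numeric vector of loss-of-suitable-area fractions in
#'   \[0, 1\]; `NA` passes through.
#' @return Character vector of projected categories.
#' @export
reclassify_threat <- function(lsa) {
  ok <- is.na(lsa) | (lsa >= 0 & lsa <= 1)
  if (!all(ok)) abort("LSA must lie in [0, 1]")
  ifelse(is.na(lsa), NA_character_,
  ifelse(lsa == 1, "EX",
  ifelse(lsa >= 0.8, "CR",
  ifelse(lsa >= 0.5, "EN",
  ifelse(lsa >= 0.3, "VU", "CC")))))
}

#' Climate-impact summary for one scenario
#'
#' Cross-tabulates currently unthreatened species (NT, CC) by the threat
#' category projected from their LSA (only CR/EN/VU count as upgrades;
#' threatened species' LSAs are reported but their categories are never
#' downgraded), with percentages over the full checklist. Also reports
#' contraction/expansion proportions among assessed species and the counts
#' of species losing more than 10/30/60% of suitable area or shifting more
#' than 60%.
#'
#' @param hc Output of [habitat_change()].
#' @param checklist Checklist data.frame (see [species_subset()]).
#' @return A list with elements `upgrades` (data.frame current x projected
#'   with `count` and `pct`), `change` (data.frame of change-class counts
#'   and proportions among assessed species), `exceedance` (named counts
#'   `lsa_gt_10`, `lsa_gt_30`, `lsa_gt_60`, `shift_gt_60`, `extinct`),
#'   `n_assessed`, `n_checklist`.
#' @export
impact_summary <- function(hc, checklist) {
  n_total <- nrow(checklist)
  cat_now <- checklist$category[match(hc$species_id, checklist$species_id)]
  hc$category <- as.character(cat_now)
  hc$projected <- reclassify_threat(hc$lsa)
  assessed <- hc[hc$assessable, , drop = FALSE]
  upg <- expand.grid(current = c("CC", "NT"), projected = c("CR", "EN", "VU"),
                     stringsAsFactors = FALSE)
  upg$count <- mapply(function(cu, pr)
    sum(assessed$category == cu & assessed$projected == pr, na.rm = TRUE),
    upg$current, upg$projected)
  upg$pct <- pct(upg$count, n_total)
  chg <- as.data.frame(table(factor(assessed$change,
                                    levels = c("contraction", "no_change", "expansion"))),
                       stringsAsFactors = FALSE)
  names(chg) <- c("change", "count")
  chg$proportion <- if (nrow(assessed)) chg$count / nrow(assessed) else NA_real_
  exceedance <- c(lsa_gt_10 = sum(assessed$lsa > 0.10),
                  lsa_gt_30 = sum(assessed$lsa > 0.30),
                  lsa_gt_60 = sum(assessed$lsa > 0.60),
                  shift_gt_60 = sum(assessed$shift > 0.60),
                  extinct = sum(assessed$lsa == 1))
  list(upgrades = upg, change = chg, exceedance = exceedance,
       n_assessed = nrow(assessed), n_checklist = n_total)
}
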