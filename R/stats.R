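#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper around the standard tie-corrected rank test (chi-square
#' approximation with k-1 degrees of freedom), with the convention that a
#' completely tied sample yields `H = 0, p = 1` rather than an error.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (>= 2 non-empty groups).
#' @return List with `H`, `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups[!is.na(values)])
  values <- values[!is.na(values)]
  if (nlevels(groups) < 2) stop("need >= 2 non-empty groups")
  if (length(unique(values)) == 1)
    return(list(H = 0, p = 1, df = nlevels(groups) - 1, n = length(values)))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(values))
}

#' Nemenyi all-pairs post hoc test after Kruskal-Wallis
#'
#' All-pairs comparison of mean ranks using the studentized-range
#' distribution (the standard Nemenyi form following a Kruskal-Wallis
#' omnibus). Groups with fewer than `min_n` observations are flagged
#' (`NA` row/column) while the remaining pairs are computed. The returned
#' matrix is symmetric with unit diagonal.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor.
#' @param min_n Minimum group size for a comparable group.
#' @return Symmetric matrix of pairwise p-values.
#' @export
nemenyi_posthoc <- function(values, groups, min_n = 2L) {
  groups <- factor(groups)
  keep <- !is.na(values)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 groups")
  rk <- rank(values)
  n_i <- tapply(rk, groups, length)
  R_i <- tapply(rk, groups, mean)
  N <- length(values)
  lev <- levels(groups)
  P <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  diag(P) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (n_i[i] < min_n || n_i[j] < min_n) next
    se <- sqrt(N * (N + 1) / 12 * (1 / n_i[i] + 1 / n_i[j]))
    q <- abs(R_i[i] - R_i[j]) / se * sqrt(2)
    p <- ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    P[i, j] <- P[j, i] <- p
  }
  P
}

#' Shapiro-Wilk normality gate
#'
#' Logs the Shapiro-Wilk verdict used to justify the nonparametric path:
#' `normal = FALSE` when `p < alpha`. Degenerate samples (n < 3 or
#' constant) default to the nonparametric path with a flag.
#'
#' @param values Numeric vector.
#' @param alpha Significance level.
#' @return List with `W`, `p`, `normal`, `degenerate`.
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(unique(values)) == 1)
    return(list(W = NA_real_, p = NA_real_, normal = FALSE,
                degenerate = TRUE))
  if (length(values) > 5000) values <- values[seq_len(5000)]
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value,
       normal = sw$p.value >= alpha, degenerate = FALSE)
}

#' Inter-region ratios of trabecular variables for one specimen
#'
#' The three pairwise region ratios per variable, with fixed orientation
#' base/metaphysis, base/epiphysis, metaphysis/epiphysis. Ratios involving
#' a missing region (e.g. an unossified epiphysis) or a zero denominator
#' are `NA`, never infinite.
#'
#' @param record Data frame with one row per region (columns `region` and
#'   the variables).
#' @param variables Variable columns to ratio.
#' @return One-row data frame of ratios named `<var>_<regionA>_<regionB>`.
#' @export
compute_ratios <- function(record,
                           variables = c("bvtv", "da", "tb_th", "tb_sp",
                                         "tb_n")) {
  pick <- function(rg, v) {
    x <- record[[v]][record$region == rg]
    if (length(x) != 1 || is.na(x)) NA_real_ else x
  }
  pairs <- list(c("base", "metaphysis"), c("base", "epiphysis"),
                c("metaphysis", "epiphysis"))
  if (sum(c("base", "metaphysis", "epiphysis") %in% record$region) < 2)
    stop("need at least two regions")
  out <- list()
  for (v in variables) for (pr in pairs) {
    num <- pick(pr[1], v)
    den <- pick(pr[2], v)
    val <- if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
    out[[paste(v, pr[1], pr[2], sep = "_")]] <- val
  }
  as.data.frame(out)
}

#' Principal component analysis of a cohort's trabecular variables
#'
#' Centres and unit-variance-scales the complete-case data matrix and
#' decomposes it by SVD. Two analyses are supported: `base_metaphysis`
#' (the 10 base+metaphysis variables) and `epiphysis` (its 5 variables).
#' Constant columns are dropped with a warning. Loading signs follow a
#' deterministic convention: each loading vector's largest-magnitude entry
#' is positive.
#'
#' @param cohort Cohort tibble (one row per specimen x region, columns
#'   `specimen_id`, `region`, variables).
#' @param which `"base_metaphysis"` or `"epiphysis"`.
#' @param variables Variables entering the analysis per region.
#' @return A `pca_report`: `loadings`, `prop_variance`, `scores`,
#'   `which`, `n`.
#' @export
run_pca <- function(cohort, which = c("base_metaphysis", "epiphysis"),
                    variables = c("bvtv", "da", "tb_th", "tb_n", "tb_sp")) {
  which <- match.arg(which)
  regions <- if (which == "base_metaphysis") c("base", "metaphysis")
             else "epiphysis"
  wide <- cohort_wide(cohort, regions, variables)
  x <- as.matrix(wide[, -1, drop = FALSE])
  cc <- complete.cases(x)
  x <- x[cc, , drop = FALSE]
  ids <- wide$specimen_id[cc]
  keep <- apply(x, 2, function(col) sd(col) > 0)
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) < 1) stop("no varying variables")
  if (nrow(x) < ncol(x))
    warning("fewer complete rows (", nrow(x), ") than variables (", ncol(x),
            "); only ", nrow(x) - 1, " components are estimable")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {  # sign convention
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = rot,
                 prop_variance = pc$sdev^2 / sum(pc$sdev^2),
                 scores = data.frame(specimen_id = ids, scores,
                                     row.names = NULL),
                 which = which, n = nrow(x)),
            class = "pca_report")
}

# wide matrix: one row per specimen, columns <region>_<variable>
cohort_wide <- function(cohort, regions, variables) {
  ids <- unique(cohort$specimen_id)
  out <- data.frame(specimen_id = ids)
  for (rg in regions) for (v in variables) {
    col <- paste(rg, v, sep = "_")
    sub <- cohort[cohort$region == rg, c("specimen_id", v)]
    out[[col]] <- sub[[v]][match(ids, sub$specimen_id)]
  }
  out
}

#' Run the full ontogenetic statistics study on a cohort table
#'
#' For every variable x region: the Shapiro-Wilk gate, the species-pooled
#' Kruskal-Wallis test across age categories with Nemenyi post hoc
#' pairwise p-values; per-category interspecific comparisons (merging
#' Neonate into Infant 1 when the Neonate cell is smaller than
#' `merge_neonate_below`); Kruskal-Wallis tests of the three inter-region
#' ratios across age categories; and the two PCAs. Significance threshold
#' `alpha = 0.05`. Cells that cannot be tested are reported with an
#' explicit reason, never silently dropped.
#'
#' @param cohort Cohort tibble (see [make_cohort()]).
#' @param alpha Significance level.
#' @param merge_neonate_below Minimum Neonate n per species before merging
#'   into Infant 1 for interspecific testing.
#' @param variables Trabecular variables to test.
#' @return A `study_report` list of tibbles: `normality`, `pooled_age`,
#'   `pooled_pairwise`, `interspecific`, `ratios`, `ratio_tests`,
#'   `pca_base_metaphysis`, `pca_epiphysis`, `notes`.
#' @export
run_study <- function(cohort, alpha = 0.05, merge_neonate_below = 3L,
                      variables = c("bvtv", "da", "tb_th", "tb_sp", "tb_n")) {
  cohort$age_category <- factor(cohort$age_category, levels = AGE_CATEGORIES)
  regions <- intersect(c("base", "metaphysis", "epiphysis"),
                       unique(cohort$region))
  notes <- character()

  normality <- list()
  pooled <- list()
  pairwise <- list()
  inter <- list()
  for (rg in regions) {
    sub <- cohort[cohort$region == rg, ]
    for (v in variables) {
      vals <- sub[[v]]
      sw <- shapiro_gate(vals, alpha)
      normality[[length(normality) + 1]] <- data.frame(
        region = rg, variable = v, W = sw$W, p = sw$p, normal = sw$normal)
      gr <- droplevels(sub$age_category[!is.na(vals)])
      if (nlevels(gr) < 2 || sum(!is.na(vals)) < 3) {
        pooled[[length(pooled) + 1]] <- data.frame(
          region = rg, variable = v, H = NA_real_, p = NA_real_,
          significant = NA, reason = "fewer than 2 age categories with data")
        next
      }
      kw <- kruskal_wallis(vals, sub$age_category)
      pooled[[length(pooled) + 1]] <- data.frame(
        region = rg, variable = v, H = kw$H, p = kw$p,
        significant = kw$p < alpha, reason = NA_character_)
      P <- nemenyi_posthoc(vals, sub$age_category)
      pw <- as.data.frame(as.table(P), stringsAsFactors = FALSE)
      names(pw) <- c("category_a", "category_b", "p")
      pw <- pw[as.integer(factor(pw$category_a, levels = rownames(P))) <
                 as.integer(factor(pw$category_b, levels = rownames(P))), ]
      pw$region <- rg
      pw$variable <- v
      pairwise[[length(pairwise) + 1]] <- pw

      # interspecific: per age category, Neonate merged into Infant1 when small
      sub2 <- sub[!is.na(vals), ]
      cat2 <- as.character(sub2$age_category)
      merged <- FALSE
      if (any(cat2 == "Neonate")) {
        n_neo <- suppressWarnings(
          min(table(factor(sub2$species)[cat2 == "Neonate"])))
        if (!is.finite(n_neo) || n_neo < merge_neonate_below) {
          cat2[cat2 == "Neonate"] <- "Infant1"
          merged <- TRUE
        }
      }
      for (ct in unique(cat2)) {
        s3 <- sub2[cat2 == ct, ]
        lbl <- if (merged && ct == "Infant1") "Neonate+Infant1" else ct
        tb <- table(factor(s3$species))
        if (length(tb[tb > 0]) < 2 || any(tb[tb > 0] < 2)) {
          inter[[length(inter) + 1]] <- data.frame(
            region = rg, variable = v, age_category = lbl, p = NA_real_,
            significant = NA, reason = "insufficient per-species sample")
          next
        }
        kw2 <- kruskal_wallis(s3[[v]], s3$species)
        inter[[length(inter) + 1]] <- data.frame(
          region = rg, variable = v, age_category = lbl, p = kw2$p,
          significant = kw2$p < alpha, reason = NA_character_)
      }
    }
  }
  if (!"epiphysis" %in% regions)
    notes <- c(notes, "no epiphysis data in cohort: epiphysis tables empty")

  # per-specimen inter-region ratios and their age tests
  ids <- unique(cohort$specimen_id)
  rat <- do.call(rbind, lapply(ids, function(id) {
    rec <- cohort[cohort$specimen_id == id, ]
    if (sum(c("base", "metaphysis", "epiphysis") %in% rec$region) < 2)
      return(NULL)
    cbind(data.frame(specimen_id = id,
                     age_category = rec$age_category[1],
                     species = rec$species[1]),
          compute_ratios(rec, variables))
  }))
  ratio_tests <- list()
  if (!is.null(rat)) {
    for (col in setdiff(names(rat), c("specimen_id", "age_category",
                                      "species"))) {
      vals <- rat[[col]]
      gr <- droplevels(factor(rat$age_category[!is.na(vals)],
                              levels = AGE_CATEGORIES))
      if (nlevels(gr) < 2) {
        ratio_tests[[length(ratio_tests) + 1]] <- data.frame(
          ratio = col, H = NA_real_, p = NA_real_, significant = NA,
          reason = "fewer than 2 age categories with data")
        next
      }
      kw <- kruskal_wallis(vals, rat$age_category)
      ratio_tests[[length(ratio_tests) + 1]] <- data.frame(
        ratio = col, H = kw$H, p = kw$p, significant = kw$p < alpha,
        reason = NA_character_)
    }
  }

  pca_bm <- tryCatch(run_pca(cohort, "base_metaphysis", variables),
                     error = function(e) {
                       notes <<- c(notes, paste("base+metaphysis PCA:",
                                                conditionMessage(e)))
                       NULL
                     })
  pca_ep <- tryCatch(run_pca(cohort, "epiphysis", variables),
                     error = function(e) {
                       notes <<- c(notes, paste("epiphysis PCA:",
                                                conditionMessage(e)))
                       NULL
                     })

  structure(list(
    normality = tibble::as_tibble(do.call(rbind, normality)),
    pooled_age = tibble::as_tibble(do.call(rbind, pooled)),
    pooled_pairwise = tibble::as_tibble(do.call(rbind, pairwise)),
    interspecific = tibble::as_tibble(do.call(rbind, inter)),
    ratios = if (is.null(rat)) NULL else tibble::as_tibble(rat),
    ratio_tests = tibble::as_tibble(do.call(rbind, ratio_tests)),
    pca_base_metaphysis = pca_bm,
    pca_epiphysis = pca_ep,
    alpha = alpha,
    notes = notes), class = "study_report")
}

#' Write a study report's tables as CSV files
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("normality", "pooled_age", "pooled_pairwise", "interspecific",
               "ratios", "ratio_tests")) {
    tb <- report[[nm]]
    if (is.null(tb)) next
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tb, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in c("pca_base_metaphysis", "pca_epiphysis")) {
    pr <- report[[nm]]
    if (is.null(pr)) next
    p <- file.path(dir, paste0(nm, "_loadings.csv"))
    write.csv(data.frame(variable = rownames(pr$loadings), pr$loadings,
                         row.names = NULL), p, row.names = FALSE)
    p2 <- file.path(dir, paste0(nm, "_scores.csv"))
    write.csv(pr$scores, p2, row.names = FALSE)
    paths <- c(paths, p, p2)
  }
  if (length(report$notes))
    writeLines(report$notes, file.path(dir, "notes.txt"))
  invisible(paths)
}
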