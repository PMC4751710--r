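## enrichment module: the statistical core. Length-normalized coverage means
## are log-transformed and compared between query and background per track by
## a Welch two-sample t-test, Bonferroni-corrected over the tracks actually
## tested; a parametric z-score serves single-region exploration.

#' Enrichment configuration
#'
#' Bundles the tunable parameters of an enrichment run.
#'
#' @param pseudocount additive constant (coverage units) before the log
#'   transform; default 0.01 preserves contrast among sub-1 mean coverages
#'   typical of normalized tracks. Must be > 0.
#' @param log_base base of the log transform (default 2). The choice is
#'   provably irrelevant to the t statistic and p-value -- a base change
#'   rescales both samples by the same constant.
#' @param n_background default background size; 1000 random gene promoters.
#' @param promoter_upstream,promoter_downstream promoter window in bp
#'   (defaults 1000/1000).
#' @param profile_halfwidth half-width of coverage profiles in bp (default
#'   1000, i.e. 2000 bp around the interval center).
#' @param alpha significance threshold on the Bonferroni-corrected p.
#' @param seed integer seed for background sampling.
#' @param test_sides 1 or 2 (default 2; direction is read from the fold
#'   difference).
#' @return a list of class `enrichment_config`.
#' @export
enrichment_config <- function(pseudocount = 0.01, log_base = 2,
                              n_background = 1000,
                              promoter_upstream = 1000, promoter_downstream = 1000,
                              profile_halfwidth = 1000,
                              alpha = 0.05, seed = 1L, test_sides = 2) {
  stopifnot(pseudocount > 0, log_base > 1, n_background >= 2,
            alpha > 0, alpha < 1, test_sides %in% c(1, 2))
  structure(list(pseudocount = pseudocount, log_base = log_base,
                 n_background = n_background,
                 promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 profile_halfwidth = profile_halfwidth,
                 alpha = alpha, seed = as.integer(seed), test_sides = test_sides),
            class = "enrichment_config")
}

#' Log-transform coverage values
#'
#' Element-wise `log_base(value + pseudocount)`. Length normalization is
#' already embodied in [mean_coverage()] (sum over the interval divided by
#' its length), so this completes the variance-stabilizing transform applied
#' before the t-test.
#'
#' @param values non-negative coverage vector.
#' @param config an [enrichment_config()] (only `pseudocount` and `log_base`
#'   are used).
#' @return transformed vector.
#' @export
log_transform <- function(values, config = enrichment_config()) {
  if (any(values < 0)) stop_input("log_transform: negative coverage value")
  log(values + config$pseudocount, base = config$log_base)
}

#' Welch two-sample t-test
#'
#' The unequal-variance t statistic
#' \deqn{t = (\bar x - \bar y) / \sqrt{s_x^2/n_x + s_y^2/n_y}}
#' with Welch--Satterthwaite degrees of freedom, chosen over the pooled
#' Student test because query and background sets routinely differ in size
#' (e.g. 24 versus 1000) and variance. Degenerate inputs are defined rather
#' than fatal: both variances zero with equal means gives t = 0, p = 1;
#' both zero with different means gives p = 0 and `degenerate = TRUE`.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param sides 1 or 2 (default 2).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
welch_t_test <- function(x, y, sides = 2) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_input("welch_t_test: each sample needs at least 2 observations")
  }
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  delta <- mean(x) - mean(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (delta == 0) return(list(t = 0, df = nx + ny - 2, p = 1, degenerate = TRUE))
    return(list(t = sign(delta) * Inf, df = nx + ny - 2, p = 0, degenerate = TRUE))
  }
  tstat <- delta / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- if (sides == 2) 2 * stats::pt(-abs(tstat), df) else stats::pt(-tstat, df)
  list(t = tstat, df = df, p = min(p, 1), degenerate = FALSE)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` where `m` is the number of tracks actually tested in the
#' run (after any category filter), so the correction matches the family of
#' hypotheses evaluated.
#'
#' @param p raw p-value(s) in \[0, 1\].
#' @param m number of tests, >= 1.
#' @return corrected p-value(s).
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0), all(p <= 1))
  pmin(1, p * m)
}

#' Fold difference between query and background coverage
#'
#' `(query_mean + epsilon) / (background_mean + epsilon)` on the raw
#' (un-logged) means; `epsilon` defaults to the pseudocount and prevents
#' division by zero, making the all-zero case a well-defined 1.
#'
#' @param query_mean,background_mean raw mean coverages (>= 0).
#' @param epsilon small positive constant.
#' @return the ratio.
#' @export
fold_difference <- function(query_mean, background_mean, epsilon = 0.01) {
  stopifnot(all(query_mean >= 0), all(background_mean >= 0), epsilon >= 0)
  (query_mean + epsilon) / (background_mean + epsilon)
}

#' Rank a track collection by query-versus-background enrichment
#'
#' For every track: mean per-base coverage over each query and background
#' interval ([coverage_matrix()], one bigWig pass per track), log transform,
#' Welch two-sample t-test between the two samples of per-interval log
#' coverages, fold difference of the raw means, and Bonferroni correction
#' with m = number of tracks tested. The result is sorted by ascending
#' p-value, ties by descending fold difference, then track ID. Tracks whose
#' coverage is identically zero on both sets are reported with p = 1 and
#' `degenerate = TRUE` rather than dropped, so m stays honest and data
#' problems stay visible.
#'
#' @param collection a [load_collection()] result.
#' @param query,background [query_set()]s with >= 2 intervals each; the
#'   background may be the default promoter sample or any user-defined set.
#' @param config an [enrichment_config()].
#' @param aliases optional chromosome-name aliases.
#' @return a data.frame of class `enrichment_table` with columns `track_id`,
#'   `query_mean`, `background_mean`, `fold_difference`, `t_statistic`,
#'   `degrees_freedom`, `p_value`, `bonferroni_p`, `n_query`,
#'   `n_background`, `degenerate`.
#' @export
enrich_all <- function(collection, query, background,
                       config = enrichment_config(), aliases = NULL) {
  stopifnot(methods::is(query, "query_set"), methods::is(background, "query_set"))
  nq <- length(query$ranges); nb <- length(background$ranges)
  if (nq < 2L || nb < 2L) {
    stop_input("query and background each need at least 2 intervals")
  }
  all_iv <- c(query$ranges, background$ranges)
  cm <- coverage_matrix(collection, all_iv, aliases)
  qi <- seq_len(nq); bi <- nq + seq_len(nb)
  m <- nrow(collection)

  res <- lapply(seq_len(m), function(t) {
    qv <- cm[t, qi]; bv <- cm[t, bi]
    degen_zero <- all(qv == 0) && all(bv == 0)
    tt <- welch_t_test(log_transform(qv, config), log_transform(bv, config),
                       sides = config$test_sides)
    data.frame(track_id = collection$track_id[t],
               query_mean = mean(qv), background_mean = mean(bv),
               fold_difference = fold_difference(mean(qv), mean(bv),
                                                 epsilon = config$pseudocount),
               t_statistic = tt$t, degrees_freedom = tt$df,
               p_value = tt$p, bonferroni_p = NA_real_,
               n_query = nq, n_background = nb,
               degenerate = degen_zero || tt$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_value[out$degenerate & out$query_mean == 0 & out$background_mean == 0] <- 1
  out$bonferroni_p <- bonferroni(out$p_value, m)
  out <- out[order(out$p_value, -out$fold_difference, out$track_id), ]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "query_label") <- query$label
  attr(out, "background_label") <- background$label
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Single-region z-score against a background set
#'
#' Single-gene exploration mode: for each track, the log coverage of one
#' region is standardized against the background's log-coverage moments,
#' `z = (x - mean) / sd`, with a two-sided standard-normal tail p-value.
#' Tracks whose background log coverage has zero spread are flagged
#' degenerate with p = 1 (z undefined).
#'
#' @param collection a [load_collection()] result.
#' @param region a single-interval `GRanges`.
#' @param background a [query_set()] with >= 2 intervals.
#' @param config an [enrichment_config()].
#' @param aliases optional chromosome-name aliases.
#' @return data.frame sorted by ascending p with columns `track_id`,
#'   `region_value` (log), `background_mean_log`, `background_sd_log`, `z`,
#'   `p_value`, `degenerate`.
#' @export
single_region_zscore <- function(collection, region, background,
                                 config = enrichment_config(), aliases = NULL) {
  if (length(region) != 1L) stop_input("single_region_zscore: exactly one region required")
  if (length(background$ranges) < 2L) stop_input("background needs at least 2 intervals")
  cm <- coverage_matrix(collection, c(region, background$ranges), aliases)
  res <- lapply(seq_len(nrow(collection)), function(t) {
    xv <- log_transform(cm[t, 1], config)
    bv <- log_transform(cm[t, -1], config)
    mu <- mean(bv); sdv <- stats::sd(bv)
    if (sdv == 0) {
      z <- NA_real_; p <- 1; degen <- TRUE
    } else {
      z <- (xv - mu) / sdv
      p <- 2 * stats::pnorm(-abs(z))
      degen <- FALSE
    }
    data.frame(track_id = collection$track_id[t], region_value = xv,
               background_mean_log = mu, background_sd_log = sdv,
               z = z, p_value = p, degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$track_id), ]
  rownames(out) <- NULL
  out
}
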