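#' Remove highly correlated traits before feature selection
#'
#' Iteratively scans trait pairs with `|Pearson r| > threshold` in a
#' deterministic order (descending `|r|`, ties broken by trait name) and
#' drops, from each offending pair, the member with the larger mean
#' absolute correlation to all other remaining traits (ties again broken
#' by name, dropping the later one). Repeats until no pair exceeds the
#' threshold.
#'
#' @param x Accession x trait matrix.
#' @param threshold Absolute-correlation cutoff in `(0, 1]` (default
#'   0.9).
#' @return List with `kept` (character vector), `dropped` (`data.frame`
#'   with `trait`, `correlated_with`, `abs_r`) and `x` (the reduced
#'   matrix).
#' @export
prefilter_correlated <- function(x, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  x <- as.matrix(x)
  kept <- colnames(x)
  dropped <- data.frame(trait = character(0), correlated_with = character(0),
                        abs_r = numeric(0), stringsAsFactors = FALSE)
  repeat {
    if (length(kept) < 2) break
    cm <- abs(stats::cor(x[, kept, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm, na.rm = TRUE) <= threshold) break
    pairs <- which(upper.tri(cm) & cm > threshold, arr.ind = TRUE)
    pr <- data.frame(a = kept[pairs[, 1]], b = kept[pairs[, 2]],
                     r = cm[pairs], stringsAsFactors = FALSE)
    pr <- pr[order(-pr$r, pr$a, pr$b), , drop = FALSE]
    a <- pr$a[1]; b <- pr$b[1]
    mean_abs <- (rowSums(cm) - 0) / (length(kept) - 1)  # diag already 0
    victim <- if (mean_abs[a] > mean_abs[b]) a
    else if (mean_abs[b] > mean_abs[a]) b
    else sort(c(a, b))[2]
    dropped <- rbind(dropped, data.frame(
      trait = victim, correlated_with = setdiff(c(a, b), victim),
      abs_r = pr$r[1], stringsAsFactors = FALSE))
    kept <- setdiff(kept, victim)
  }
  list(kept = kept, dropped = dropped, x = x[, kept, drop = FALSE])
}

#' Shadow-feature (Boruta) selection of traits predicting group membership
#'
#' All-relevant feature selection around a random-forest classifier. Each
#' iteration appends a shuffled copy ("shadow") of every still-undecided
#' trait, fits a random forest (ranger, permutation importance on
#' out-of-bag samples), and scores a "hit" for every trait whose
#' importance exceeds the maximum shadow importance. After each iteration
#' a two-sided binomial test (success probability 0.5) on the hit count,
#' Bonferroni-corrected across currently-undecided traits, confirms
#' traits with significantly more hits and rejects traits with
#' significantly fewer. Traits still undecided at `max_runs` are
#' tentative.
#'
#' @param x Accession x trait matrix (no missing values).
#' @param y Group label per accession (>= 2 groups, each with >= 2
#'   members).
#' @param alpha Significance threshold before Bonferroni correction
#'   (default 0.05).
#' @param max_runs Maximum iterations (default 1000; the benchmark suites
#'   use fewer since decisions typically settle within a few dozen
#'   iterations).
#' @param num_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @return Object of class `boruta_result`: `decision` (named factor with
#'   levels confirmed/tentative/rejected), `mean_importance`,
#'   `hit_counts`, `n_iterations_run`, `alpha`, `seed`.
#' @export
boruta_select <- function(x, y, alpha = 0.05, max_runs = 1000L,
                          num_trees = 500L, seed = 1L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("x contains missing values")
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 groups")
  if (any(table(y) < 2)) stop("group with a single member: cannot classify")
  traits <- colnames(x)
  p <- length(traits)
  decision <- stats::setNames(rep("tentative", p), traits)
  hits <- stats::setNames(integer(p), traits)
  n_tested <- stats::setNames(integer(p), traits)
  imp_sum <- stats::setNames(numeric(p), traits)
  run <- 0L
  while (run < max_runs && any(decision == "tentative")) {
    run <- run + 1L
    und <- traits[decision == "tentative"]
    set.seed(seed + run)
    shadows <- apply(x[, und, drop = FALSE], 2, sample)
    colnames(shadows) <- paste0("shadow_", und)
    dat <- data.frame(x[, und, drop = FALSE], shadows, check.names = FALSE)
    dat$.group <- y
    rf <- ranger::ranger(
      dependent.variable.name = ".group", data = dat,
      num.trees = num_trees, importance = "permutation",
      num.threads = 1, seed = seed + run,
      respect.unordered.factors = "order")
    imp <- rf$variable.importance
    shadow_max <- max(imp[paste0("shadow_", und)])
    real_imp <- imp[und]
    hits[und] <- hits[und] + as.integer(real_imp > shadow_max)
    n_tested[und] <- n_tested[und] + 1L
    imp_sum[und] <- imp_sum[und] + real_imp
    # two-sided binomial tests with Bonferroni over undecided traits
    bonf_alpha <- alpha / length(und)
    for (tr in und) {
      h <- hits[tr]; t <- n_tested[tr]
      p_two <- 2 * min(stats::pbinom(h, t, 0.5),
                       stats::pbinom(h - 1, t, 0.5, lower.tail = FALSE))
      p_two <- min(1, p_two)
      if (p_two <= bonf_alpha)
        decision[tr] <- if (h / t > 0.5) "confirmed" else "rejected"
    }
  }
  mean_imp <- imp_sum / pmax(n_tested, 1L)
  structure(list(decision = factor(decision,
                                   levels = c("confirmed", "tentative", "rejected")),
                 mean_importance = mean_imp, hit_counts = hits,
                 n_iterations_run = run, alpha = alpha, seed = seed),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  cat(sprintf("Boruta selection after %d iterations: %d confirmed, %d tentative, %d rejected\n",
              x$n_iterations_run, tab["confirmed"], tab["tentative"], tab["rejected"]))
  invisible(x)
}

#' Ranked trait importance table
#'
#' @param result A `boruta_result`.
#' @return `data.frame` with `trait`, `mean_importance`, `hit_counts`,
#'   `decision`, sorted by mean importance, descending.
#' @export
importance_table <- function(result) {
  ord <- order(result$mean_importance, decreasing = TRUE)
  data.frame(trait = names(result$mean_importance)[ord],
             mean_importance = unname(result$mean_importance[ord]),
             hits = unname(result$hit_counts[ord]),
             decision = as.character(result$decision[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}
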