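#' Comparison design for feature selection
#'
#' Discrete mode compares per-subject state means between pairs of emotional
#' states; transition mode compares per-subject means of the two segments
#' flanking a state transition. Relax segments count as the "neutral" flank
#' when matching transitions.
#'
#' @param mode `"discrete"` or `"transition"`.
#' @param pairs optional list of 2-element character vectors; defaults are
#'   the three state pairs (discrete) or the three protocol transitions
#'   (transition).
#' @return Object of class `comparison_design`.
#' @export
comparison_design <- function(mode = c("transition", "discrete"), pairs = NULL) {
  mode <- match.arg(mode)
  if (is.null(pairs)) {
    pairs <- if (mode == "discrete")
      list(c("neutral", "negative"), c("negative", "positive"),
           c("positive", "neutral"))
    else
      list(c("neutral", "negative"), c("negative", "neutral"),
           c("neutral", "positive"))
  }
  if (length(pairs) < 1) stop("need at least one comparison pair")
  ok <- vapply(pairs, function(p) length(p) == 2 &&
                 all(p %in% c("relax", "neutral", "negative", "positive")), TRUE)
  if (!all(ok)) stop("pairs must be 2-element vectors of state labels")
  structure(list(mode = mode, pairs = pairs), class = "comparison_design")
}

# Effective label for transition matching: relax flanks count as neutral.
effective_label <- function(label) ifelse(label == "relax", "neutral", label)

#' Per-subject paired samples across one state transition
#'
#' Finds the first segment boundary in each subject's timeline where a
#' segment with effective label `pair[1]` is immediately followed by one with
#' effective label `pair[2]` (relax segments count as neutral), and returns
#' each subject's mean feature value over the full flanking segments.
#'
#' @param fm a `feature_matrix`.
#' @param feature one registry feature name.
#' @param pair character vector `c(from, to)`.
#' @return data.frame `subject`, `before`, `after` (one row per subject;
#'   subjects lacking the transition are dropped with a warning).
#' @export
paired_samples <- function(fm, feature, pair) {
  stopifnot(feature %in% names(fm))
  segtab <- unique(fm[, c("subject", "segment", "label")])
  out <- list()
  dropped <- 0L
  for (sid in unique(fm$subject)) {
    st <- segtab[segtab$subject == sid, ]
    st <- st[order(st$segment), ]
    eff <- effective_label(st$label)
    hit <- which(eff[-length(eff)] == pair[1] & eff[-1] == pair[2] &
                   diff(st$segment) == 1)
    if (length(hit) == 0) { dropped <- dropped + 1L; next }
    g_before <- st$segment[hit[1]]
    g_after <- st$segment[hit[1] + 1L]
    b <- mean(fm[[feature]][fm$subject == sid & fm$segment == g_before])
    a <- mean(fm[[feature]][fm$subject == sid & fm$segment == g_after])
    out[[length(out) + 1L]] <- data.frame(subject = sid, before = b, after = a)
  }
  if (dropped > 0)
    warning(sprintf("%d subject(s) lack the %s->%s transition and were dropped",
                    dropped, pair[1], pair[2]))
  if (length(out) == 0) stop("no subject has the requested transition")
  do.call(rbind, out)
}

# Paired test on differences d: Shapiro-Wilk normality gate at alpha_norm,
# then paired t or Wilcoxon signed rank. Zero-variance differences -> p = 1.
paired_test <- function(d, alpha_norm = 0.05) {
  if (stats::sd(d) == 0) return(list(p = 1, test = "degenerate"))
  sw <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
  if (sw >= alpha_norm) {
    list(p = stats::t.test(d)$p.value, test = "paired_t")
  } else {
    dd <- d[d != 0]
    if (length(dd) == 0) return(list(p = 1, test = "degenerate"))
    p <- if (length(dd) < 25)
      suppressWarnings(stats::wilcox.test(dd, exact = TRUE)$p.value)
    else
      stats::wilcox.test(dd, exact = FALSE, correct = TRUE)$p.value
    list(p = p, test = "wilcoxon_signed_rank")
  }
}

selection_result <- function(table, final_subset, method, alpha) {
  structure(list(table = table, final_subset = final_subset,
                 method = method, alpha = alpha),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s (alpha=%g): %d significant, %d discarded, %d final\n",
              x$method, x$alpha, sum(x$table$significant),
              sum(x$table$discarded_redundant), length(x$final_subset)))
  if (length(x$final_subset))
    cat("  final subset:", paste(x$final_subset, collapse = ", "), "\n")
  invisible(x)
}

#' Transition-based feature selection (M3)
#'
#' For every feature and every transition of the design, forms per-subject
#' before/after segment means, gates the paired differences through a
#' Shapiro-Wilk normality test (alpha = 0.05), and applies a paired t-test
#' (normal) or Wilcoxon signed-rank test (otherwise). A feature is
#' significant when p < `alpha` in **all** transitions; significant features
#' then pass through the greedy Pearson redundancy filter in canonical
#' registry order.
#'
#' @param fm a `feature_matrix`.
#' @param design a transition-mode `comparison_design`.
#' @param alpha significance level (default 0.05).
#' @param features feature names to consider (default: full registry).
#' @param r_threshold redundancy threshold on `|r|` (default 0.9).
#' @return A `selection_result`; its `table` has one row per feature with
#'   per-transition p-values and tests, `significant`, `discarded_redundant`,
#'   `partner`, `r`.
#' @export
transition_select <- function(fm, design = comparison_design("transition"),
                              alpha = 0.05, features = NULL,
                              r_threshold = 0.9) {
  stopifnot(design$mode == "transition")
  if (is.null(features))
    features <- intersect(feature_registry()$all, names(fm))
  if (length(unique(fm$subject)) < 6)
    stop("need at least 6 subjects")
  np <- length(design$pairs)
  pmat <- matrix(NA_real_, length(features), np)
  tmat <- matrix(NA_character_, length(features), np)
  for (j in seq_len(np)) {
    pair <- design$pairs[[j]]
    for (i in seq_along(features)) {
      ps <- paired_samples(fm, features[i], pair)
      res <- paired_test(ps$after - ps$before)
      pmat[i, j] <- res$p; tmat[i, j] <- res$test
    }
  }
  sig <- apply(pmat < alpha, 1, all)
  tab <- data.frame(feature = features, significant = sig,
                    stringsAsFactors = FALSE)
  colnames(pmat) <- paste0("p_", vapply(design$pairs, paste, "", collapse = "_to_"))
  tab <- cbind(tab, as.data.frame(pmat))
  tab$test_used <- apply(tmat, 1, paste, collapse = ";")
  finalize_selection(tab, fm, "M3 (transition)", alpha, r_threshold)
}

#' Discrete-state feature selection (M1)
#'
#' Kruskal-Wallis test on the two groups of per-subject segment means for
#' each pairwise state comparison of the design; a feature is significant
#' when p < `alpha` in all comparisons, then passes the greedy redundancy
#' filter.
#'
#' @inheritParams transition_select
#' @param design a discrete-mode `comparison_design`.
#' @return A `selection_result`.
#' @export
discrete_select <- function(fm, design = comparison_design("discrete"),
                            alpha = 0.05, features = NULL,
                            r_threshold = 0.9) {
  stopifnot(design$mode == "discrete")
  if (is.null(features))
    features <- intersect(feature_registry()$all, names(fm))
  ## per-subject, per-state mean over that state's picture segments
  state_means <- function(feature, state) {
    sel <- fm$label == state
    tapply(fm[[feature]][sel], fm$subject[sel], mean)
  }
  np <- length(design$pairs)
  pmat <- matrix(NA_real_, length(features), np)
  for (j in seq_len(np)) {
    pair <- design$pairs[[j]]
    for (i in seq_along(features)) {
      g1 <- state_means(features[i], pair[1])
      g2 <- state_means(features[i], pair[2])
      if (stats::sd(c(g1, g2)) == 0) { pmat[i, j] <- 1; next }
      pmat[i, j] <- stats::kruskal.test(list(g1, g2))$p.value
    }
  }
  sig <- apply(pmat < alpha, 1, all)
  tab <- data.frame(feature = features, significant = sig,
                    stringsAsFactors = FALSE)
  colnames(pmat) <- paste0("p_", vapply(design$pairs, paste, "", collapse = "_vs_"))
  tab <- cbind(tab, as.data.frame(pmat))
  tab$test_used <- "kruskal_wallis"
  finalize_selection(tab, fm, "M1 (discrete)", alpha, r_threshold)
}

# Shared tail of M1/M3: run the redundancy filter over significant features
# (canonical order) and assemble the selection_result.
finalize_selection <- function(tab, fm, method, alpha, r_threshold) {
  reg_order <- feature_registry()$all
  cand <- tab$feature[tab$significant]
  # canonical registry order; features outside the registry keep their order
  cand <- c(reg_order[reg_order %in% cand], setdiff(cand, reg_order))
  rf <- redundancy_filter(cand, fm, r_threshold = r_threshold)
  tab$discarded_redundant <- tab$feature %in% rf$discarded$feature
  tab$partner <- rf$discarded$partner[match(tab$feature, rf$discarded$feature)]
  tab$r <- rf$discarded$r[match(tab$feature, rf$discarded$feature)]
  selection_result(tab, rf$kept, method, alpha)
}

#' Greedy Pearson redundancy filter
#'
#' Walks the candidate features in canonical registry order, keeping a
#' feature only when its absolute Pearson correlation (over pooled
#' window-level values) with every already-kept feature is `<= r_threshold`.
#' The rule is order-dependent by construction (keep-first). A constant
#' feature has undefined correlation and is kept with a flag.
#'
#' @param candidates character vector of feature names, canonical order.
#' @param fm a `feature_matrix` supplying pooled window-level values.
#' @param r_threshold threshold on `|r|` (strictly greater discards).
#' @return List: `kept` (character), `discarded` (data.frame `feature`,
#'   `partner`, `r`), `flagged_constant` (character).
#' @export
redundancy_filter <- function(candidates, fm, r_threshold = 0.9) {
  kept <- character(0)
  flagged <- character(0)
  disc <- data.frame(feature = character(0), partner = character(0),
                     r = numeric(0), stringsAsFactors = FALSE)
  for (f in candidates) {
    x <- fm[[f]]
    if (stats::sd(x) == 0 || !all(is.finite(x))) {
      kept <- c(kept, f); flagged <- c(flagged, f)
      next
    }
    rs <- vapply(kept, function(k) {
      y <- fm[[k]]
      if (stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y)
    }, numeric(1))
    bad <- which(abs(rs) > r_threshold)
    if (length(bad)) {
      j <- bad[which.max(abs(rs[bad]))]
      disc <- rbind(disc, data.frame(feature = f, partner = kept[j],
                                     r = rs[j], stringsAsFactors = FALSE))
    } else {
      kept <- c(kept, f)
    }
  }
  list(kept = kept, discarded = disc, flagged_constant = flagged)
}

#' Per-signal-group PCA reduction (M2)
#'
#' Standardises each signal group's feature block and keeps the stated
#' number of principal components per group (defaults: ECG 6, BVP 5, GSR 6,
#' total 17).
#'
#' @param fm a `feature_matrix`.
#' @param group_dims named integer vector `c(ECG=, BVP=, GSR=)`.
#' @return data.frame of component scores (columns `ECG_PC1`, ...) with the
#'   `fm` index columns prepended; attributes `loadings` and
#'   `explained_variance_ratio` (named lists per group).
#' @export
pca_reduce <- function(fm, group_dims = c(ECG = 6, BVP = 5, GSR = 6)) {
  reg <- feature_registry()
  groups <- list(ECG = reg$ecg, BVP = reg$bvp, GSR = reg$gsr)
  scores <- list(); loads <- list(); evr <- list()
  for (gname in names(group_dims)) {
    feats <- intersect(groups[[gname]], names(fm))
    d <- group_dims[[gname]]
    if (d > length(feats))
      stop(sprintf("requested %d components for %s but only %d features",
                   d, gname, length(feats)))
    X <- as.matrix(fm[, feats])
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    X <- scale(X, center = TRUE, scale = sds)
    pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
    sc <- pc$x[, seq_len(d), drop = FALSE]
    colnames(sc) <- paste0(gname, "_PC", seq_len(d))
    scores[[gname]] <- sc
    loads[[gname]] <- pc$rotation[, seq_len(d), drop = FALSE]
    evr[[gname]] <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(d)]
  }
  meta_cols <- intersect(c("subject", "segment", "label", "window",
                           "window_start_s"), names(fm))
  out <- cbind(fm[, meta_cols, drop = FALSE], do.call(cbind, scores))
  attr(out, "loadings") <- loads
  attr(out, "explained_variance_ratio") <- evr
  out
}

#' Read a printed selection-annotation table
#'
#' Long CSV format `signal,feature,method,marker` with marker vocabulary
#' `"*"` (significant), `"*(-)"` (significant but redundancy-discarded) and
#' `"-"` (not significant); the typographic variants `*(—)` and
#' `—` are accepted and normalised.
#'
#' @param path CSV path. The package ships the transcription of the
#'   published selection table as
#'   `system.file("extdata", "table1.csv", package = "transfeat")`.
#' @return data.frame of class `annotation_table`.
#' @export
read_annotation_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("signal", "feature", "method", "marker") %in% names(tbl)))
  tbl$marker <- gsub("—", "-", tbl$marker)
  ok <- tbl$marker %in% c("*", "*(-)", "-")
  if (!all(ok))
    stop("unknown marker(s): ", paste(unique(tbl$marker[!ok]), collapse = " "))
  class(tbl) <- c("annotation_table", "data.frame")
  tbl
}

#' Selection counts from a printed annotation table
#'
#' Bookkeeping of the worked example: preliminary = rows marked `*` or
#' `*(-)`; discarded = rows marked `*(-)`; final = preliminary - discarded.
#'
#' @param tbl an `annotation_table` (see [read_annotation_table()]).
#' @param method `"M1"` or `"M3"`.
#' @return List: `preliminary_count`, `discarded_count`, `final_count`,
#'   `per_signal_final` (named vector), `final_features` (character).
#' @export
selection_from_annotations <- function(tbl, method = c("M3", "M1")) {
  method <- match.arg(method)
  sub <- tbl[tbl$method == method, ]
  if (nrow(sub) == 0) stop("no rows for method ", method)
  prelim <- sub$marker %in% c("*", "*(-)")
  disc <- sub$marker == "*(-)"
  fin <- prelim & !disc
  per_signal <- vapply(c("ECG", "BVP", "GSR"),
                       function(s) sum(fin & sub$signal == s), numeric(1))
  list(preliminary_count = sum(prelim),
       discarded_count = sum(disc),
       final_count = sum(fin),
       per_signal_final = per_signal,
       final_features = sub$feature[fin])
}
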