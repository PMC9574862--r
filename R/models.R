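#' Ordinary least-squares line with R-squared
#'
#' Closed-form simple linear regression used for every descriptor-solubility
#' correlation in the workflow: slope, intercept, and
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param x,y numeric vectors (same length, n >= 3, finite).
#' @param x_name,y_name axis labels stored with the model.
#' @return object of class \code{protacsol_lm}: list with \code{x_name},
#'   \code{y_name}, \code{slope}, \code{intercept}, \code{r2}, \code{n}.
#' @section Errors: constant x raises a degenerate-design error.
#' @examples
#' fit_linear(1:5, 2 * (1:5) + 1)
#' @export
fit_linear <- function(x, y, x_name = "x", y_name = "y") {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    stop(structure(class = c("protacsol_insufficient_data_error", "error", "condition"),
                   list(message = "need >= 3 finite (x, y) pairs", call = NULL)))
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    stop(structure(class = c("protacsol_degenerate_design_error", "error", "condition"),
                   list(message = "x is constant: slope undefined", call = NULL)))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(x_name = x_name, y_name = y_name, slope = slope,
                 intercept = intercept, r2 = max(0, min(1, r2)),
                 n = length(x)),
            class = "protacsol_lm")
}

#' @export
print.protacsol_lm <- function(x, ...) {
  cat(sprintf("%s = %.4g * %s + %.4g   (R2 = %.3f, n = %d)\n",
              x$y_name, x$slope, x$x_name, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Fixed BRlogD/TPSA solubility rule
#'
#' The two-split decision rule relating the GSK solubility class to polarity
#' and lipophilicity: TPSA >= 289.31 A^2 classifies a PROTAC as highly
#' soluble; otherwise BRlogD >= 2.58 classifies it as low solubility; the
#' remaining region (TPSA < 289.31 and BRlogD < 2.58) is intermediate.
#'
#' @param tpsa numeric TPSA, squared angstroms.
#' @param brlogd numeric BRlogD.
#' @return ordered factor low < intermediate < high (vectorized).
#' @examples
#' apply_paper_rule(c(300, 200, 200), c(5, 3, 2))
#' @export
apply_paper_rule <- function(tpsa, brlogd) {
  stopifnot(all(is.finite(tpsa)), all(is.finite(brlogd)),
            length(tpsa) == length(brlogd))
  lab <- ifelse(tpsa >= 289.31, "high",
                ifelse(brlogd >= 2.58, "low", "intermediate"))
  factor(lab, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' The fixed rule as a decision-tree object
#'
#' Builds the two-split tree (root: TPSA at 289.31; left branch: BRlogD at
#' 2.58) as a \code{protacsol_tree}, so the fixed rule and refitted trees
#' share one prediction path.
#'
#' @return a \code{protacsol_tree} with provenance \code{"fixed_rule"}.
#' @export
fixed_rule_tree <- function() {
  node <- list(
    leaf = FALSE, feature = "tpsa", threshold = 289.31,
    right = list(leaf = TRUE, class = "high", n = NA_integer_),
    left = list(
      leaf = FALSE, feature = "brlogd", threshold = 2.58,
      right = list(leaf = TRUE, class = "low", n = NA_integer_),
      left = list(leaf = TRUE, class = "intermediate", n = NA_integer_)
    )
  )
  structure(list(root = node, classes = c("low", "intermediate", "high"),
                 provenance = "fixed_rule"),
            class = "protacsol_tree")
}

gini_impurity <- function(labels, classes) {
  p <- tabulate(match(labels, classes), nbins = length(classes)) / length(labels)
  1 - sum(p^2)
}

best_split <- function(X, y, classes, features, min_leaf) {
  n <- nrow(X)
  parent <- gini_impurity(y, classes) * n
  best <- NULL
  for (f in features) {
    v <- X[[f]]
    uv <- sort(unique(v))
    if (length(uv) < 2) next
    thr <- (uv[-1] + uv[-length(uv)]) / 2
    for (t in thr) {
      left <- v < t
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      cost <- gini_impurity(y[left], classes) * nl +
        gini_impurity(y[!left], classes) * nr
      if (is.null(best) || cost < best$cost - 1e-12) {
        best <- list(feature = f, threshold = t, cost = cost)
      }
    }
  }
  if (!is.null(best) && best$cost < parent - 1e-12) best else NULL
}

majority_class <- function(y, classes) {
  counts <- tabulate(match(y, classes), nbins = length(classes))
  classes[which.max(counts)] # ties: first class in level order
}

grow_node <- function(X, y, classes, depth, max_depth, min_leaf, mtry, rng) {
  if (depth >= max_depth || length(unique(y)) == 1 || nrow(X) < 2 * min_leaf) {
    return(list(leaf = TRUE, class = majority_class(y, classes), n = nrow(X)))
  }
  features <- names(X)
  if (!is.null(mtry) && mtry < length(features)) {
    features <- sort(sample(features, mtry)) # seeded upstream
  }
  sp <- best_split(X, y, classes, features, min_leaf)
  if (is.null(sp)) {
    return(list(leaf = TRUE, class = majority_class(y, classes), n = nrow(X)))
  }
  left <- X[[sp$feature]] < sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_node(X[left, , drop = FALSE], y[left], classes,
                        depth + 1, max_depth, min_leaf, mtry, rng),
       right = grow_node(X[!left, , drop = FALSE], y[!left], classes,
                         depth + 1, max_depth, min_leaf, mtry, rng))
}

#' Learn a classification tree (CART-style, Gini impurity)
#'
#' Top-down exhaustive search over candidate thresholds (midpoints of
#' consecutive sorted distinct feature values) minimizing total Gini
#' impurity; leaves are labeled by majority class. Deterministic by default;
#' the optional per-node feature subsampling (\code{mtry}) emulates the
#' "random tree" behavior of common machine-learning toolkits and is seeded.
#'
#' @param X data.frame of numeric features (e.g. TPSA, BRlogD, log kw(IAM)).
#' @param y class labels (factor or character).
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_leaf minimum observations per leaf.
#' @param mtry number of features sampled per node; NULL (default) disables
#'   subsampling and makes the learner deterministic.
#' @param seed RNG seed used only when \code{mtry} is set.
#' @return object of class \code{protacsol_tree} with elements \code{root},
#'   \code{classes}, \code{provenance = "refit"}.
#' @examples
#' X <- data.frame(x = c(1, 2, 3, 7, 8, 9))
#' y <- rep(c("A", "B"), each = 3)
#' learn_tree(X, y)$root$threshold # 5
#' @export
learn_tree <- function(X, y, max_depth = 10, min_leaf = 1, mtry = NULL,
                       seed = NULL) {
  stopifnot(is.data.frame(X), nrow(X) == length(y), nrow(X) >= 1)
  stopifnot(all(vapply(X, is.numeric, logical(1))))
  if (anyNA(X) || anyNA(y)) stop("features and labels must be complete")
  classes <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  y <- as.character(y)
  if (length(unique(y)) == 1) {
    warning("single-class input: returning a single-leaf tree")
  }
  if (!is.null(seed)) set.seed(seed)
  root <- grow_node(X, y, classes, depth = 0, max_depth = max_depth,
                    min_leaf = min_leaf, mtry = mtry)
  structure(list(root = root, classes = classes, provenance = "refit"),
            class = "protacsol_tree")
}

predict_node <- function(node, row) {
  while (!node$leaf) {
    node <- if (row[[node$feature]] < node$threshold) node$left else node$right
  }
  node$class
}

#' @export
predict.protacsol_tree <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  lab <- vapply(seq_len(nrow(newdata)), function(i) {
    predict_node(object$root, newdata[i, , drop = FALSE])
  }, character(1))
  factor(lab, levels = object$classes,
         ordered = identical(object$classes, c("low", "intermediate", "high")))
}

tree_splits <- function(node) {
  if (node$leaf) return(NULL)
  rbind(data.frame(feature = node$feature, threshold = node$threshold,
                   stringsAsFactors = FALSE),
        tree_splits(node$left), tree_splits(node$right))
}

#' @export
print.protacsol_tree <- function(x, ...) {
  cat("Decision tree (", x$provenance, "), classes: ",
      paste(x$classes, collapse = " < "), "\n", sep = "")
  show_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, "-> ", node$class, "\n", sep = "")
    } else {
      cat(pad, node$feature, " < ", format(node$threshold), "\n", sep = "")
      show_node(node$left, indent + 1)
      cat(pad, node$feature, " >= ", format(node$threshold), "\n", sep = "")
      show_node(node$right, indent + 1)
    }
  }
  show_node(x$root, 1)
  invisible(x)
}

#' Export / import a decision-tree model as JSON
#'
#' @param tree a \code{protacsol_tree}.
#' @param path file path.
#' @return \code{read_tree} returns the restored \code{protacsol_tree}.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "protacsol_tree"))
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  fix <- function(node) {
    node$leaf <- isTRUE(node$leaf)
    if (!node$leaf) {
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    }
    node
  }
  obj$root <- fix(obj$root)
  obj$classes <- unlist(obj$classes)
  structure(obj, class = "protacsol_tree")
}

#' Confusion matrix with accuracy and per-class recall
#'
#' @param truth,pred class labels (coerced to a common factor).
#' @param classes optional explicit class levels.
#' @return list with \code{table} (rows = truth, columns = predicted),
#'   \code{accuracy}, \code{recall} (named per class).
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) {
    classes <- union(levels(factor(truth)), levels(factor(pred)))
  }
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  tab <- table(truth = truth, predicted = pred)
  acc <- sum(diag(tab)) / sum(tab)
  recall <- diag(tab) / rowSums(tab)
  list(table = tab, accuracy = acc, recall = recall)
}

make_folds <- function(y, k, stratified) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' k-fold cross-validation of the tree classifier
#'
#' Stratified k-fold partition (plain k-fold with a warning when some class
#' has fewer members than folds), per-fold fit and predict, pooled confusion
#' matrix; accuracy is pooled correct / n, averaged over repeats.
#'
#' @param X data.frame of numeric features.
#' @param y class labels.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param repeats number of repeated partitions (default 1).
#' @param ... passed to \code{\link{learn_tree}}.
#' @return list with \code{accuracy} (mean over repeats), \code{confusion}
#'   (pooled over all repeats), \code{per_repeat} accuracies.
#' @export
cross_validate <- function(X, y, k = 10, seed = 1, repeats = 1, ...) {
  stopifnot(nrow(X) == length(y))
  n <- length(y)
  if (k > n) {
    stop(structure(class = c("protacsol_fold_error", "error", "condition"),
                   list(message = "k exceeds the number of observations", call = NULL)))
  }
  classes <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  ych <- as.character(y)
  stratified <- all(table(factor(ych, levels = classes)) >= 1) &&
    min(table(ych)) >= k
  if (!stratified) {
    warning("some class has fewer members than folds: using plain k-fold")
  }
  set.seed(seed)
  acc <- numeric(repeats)
  pooled_truth <- pooled_pred <- character(0)
  for (r in seq_len(repeats)) {
    fold <- make_folds(ych, k, stratified)
    pred <- character(n)
    for (f in seq_len(k)) {
      test <- fold == f
      if (!any(test)) next
      tr <- learn_tree(X[!test, , drop = FALSE], factor(ych[!test], levels = classes), ...)
      pred[test] <- as.character(predict(tr, X[test, , drop = FALSE]))
    }
    acc[r] <- mean(pred == ych)
    pooled_truth <- c(pooled_truth, ych)
    pooled_pred <- c(pooled_pred, pred)
  }
  list(accuracy = mean(acc),
       confusion = confusion_matrix(pooled_truth, pooled_pred, classes),
       per_repeat = acc)
}

#' Chemical-space export for 3D scatter plots
#'
#' Long-format table (id, x, y, z, gsk_class, censored) over a chosen
#' descriptor triple: the survey space (nc, phi, tpsa) or the
#' classification space (log_kw_iam, brlogd, tpsa). Compounds missing any
#' requested axis are dropped with a warning.
#'
#' @param dataset a \code{protac_dataset}.
#' @param axes character(3): descriptor column names.
#' @return data.frame with columns \code{id}, \code{x}, \code{y}, \code{z},
#'   \code{gsk_class}, \code{censored}; axis names kept as attribute
#'   \code{axes}.
#' @export
chemical_space_export <- function(dataset,
                                  axes = c("log_kw_iam", "brlogd", "tpsa")) {
  stopifnot(inherits(dataset, "protac_dataset"), length(axes) == 3)
  d <- dataset$descriptors
  miss <- setdiff(axes, names(d))
  if (length(miss) > 0) stop("descriptor column(s) not present: ",
                             paste(miss, collapse = ", "))
  sol <- dataset$solubility
  out <- data.frame(id = d$id,
                    x = d[[axes[1]]], y = d[[axes[2]]], z = d[[axes[3]]],
                    stringsAsFactors = FALSE)
  keep <- stats::complete.cases(out[, c("x", "y", "z")])
  if (any(!keep)) {
    warning("dropping compound(s) with missing axis value: ",
            paste(out$id[!keep], collapse = ", "))
    out <- out[keep, , drop = FALSE]
  }
  m <- match(out$id, sol$compound_id)
  out$gsk_class <- sol$gsk_class[m]
  out$censored <- sol$censored[m]
  attr(out, "axes") <- axes
  out
}

# Interval representation of a possibly censored log S value:
# censor "none" -> [v, v]; "below" -> (-Inf, v]; "above" -> [v, Inf).
censored_interval <- function(value, censor) {
  if (is.na(value)) return(c(-Inf, Inf))
  switch(censor,
         none = c(value, value),
         below = c(-Inf, value),
         above = c(value, Inf),
         stop("censor must be one of none/below/above"))
}

#' Compare a PROTAC pair against its varied building block
#'
#' For two PROTACs differing in exactly one moiety (warhead, linker, or E3
#' ligand), computes the PROTAC solubility difference and checks whether the
#' solubility ordering of the varied building blocks is concordant with the
#' ordering of the PROTACs. Censored building-block values are treated as
#' half-open intervals, so an ordering is still decided when the intervals do
#' not overlap; otherwise the pair is indeterminate.
#'
#' @param pair_ids character(2): ids of PROTACs A and B.
#' @param varied one of \code{"warhead"}, \code{"linker"},
#'   \code{"e3_ligand"}.
#' @param protac_sol data.frame: \code{compound_id}, \code{log_s},
#'   \code{censored} (logical).
#' @param bb_table data.frame of the varied building blocks:
#'   \code{protac_id}, \code{bb_id}, \code{log_s}, \code{censor}
#'   (\code{"none"}, \code{"below"}, \code{"above"}), and optionally
#'   \code{brlogd}, \code{log_kw_iam}, \code{tpsa}.
#' @return object of class \code{protacsol_pair}: list with \code{pair_ids},
#'   \code{varied}, \code{delta_log_s} (A - B), \code{bb_delta} (named
#'   numeric deltas where both values are exact), \code{concordance}.
#' @export
compare_pair <- function(pair_ids, varied, protac_sol, bb_table) {
  stopifnot(length(pair_ids) == 2,
            varied %in% c("warhead", "linker", "e3_ligand"))
  m <- match(pair_ids, protac_sol$compound_id)
  if (anyNA(m)) {
    stop(structure(class = c("protacsol_reference_error", "error", "condition"),
                   list(message = paste0("unknown PROTAC id(s): ",
                                         paste(pair_ids[is.na(m)], collapse = ", ")),
                        call = NULL)))
  }
  ps <- protac_sol[m, ]
  delta <- ps$log_s[1] - ps$log_s[2]
  bmatch <- match(pair_ids, bb_table$protac_id)
  bb <- bb_table[bmatch, ]
  prop_delta <- c()
  for (p in intersect(c("log_s", "brlogd", "log_kw_iam", "tpsa"), names(bb))) {
    ok <- if (p == "log_s") all(bb$censor == "none") else TRUE
    if (ok && !anyNA(bb[[p]])) {
      prop_delta[paste0("bb_delta_", p)] <- bb[[p]][1] - bb[[p]][2]
    }
  }
  concordance <- "indeterminate"
  if (identical(pair_ids[1], pair_ids[2]) || isTRUE(all.equal(delta, 0))) {
    concordance <- "indeterminate"
  } else if (!anyNA(bmatch) && !any(ps$censored)) {
    iA <- censored_interval(bb$log_s[1], bb$censor[1])
    iB <- censored_interval(bb$log_s[2], bb$censor[2])
    bb_order <- if (iA[1] > iB[2]) 1 else if (iB[1] > iA[2]) -1 else 0
    if (bb_order != 0) {
      concordance <- if (sign(delta) == bb_order) "concordant" else "discordant"
    }
  }
  structure(list(pair_ids = pair_ids, varied = varied, delta_log_s = delta,
                 bb_ids = bb$bb_id, bb_delta = prop_delta,
                 concordance = concordance),
            class = "protacsol_pair")
}

#' @export
print.protacsol_pair <- function(x, ...) {
  cat(sprintf("pair %s vs %s (varied: %s): delta log S = %+.2f, %s\n",
              x$pair_ids[1], x$pair_ids[2], x$varied, x$delta_log_s,
              x$concordance))
  invisible(x)
}

#' Build the classification matrix of a study
#'
#' Assembles the feature matrix and GSK class labels used by the tree
#' learner from a dataset, as configuration rather than hard-code: compounds
#' can be excluded by id (e.g. a graphically misclassified outlier), and
#' censored measurements can be kept (as low-class instances) or dropped.
#'
#' @param dataset a \code{protac_dataset} with descriptors and solubility.
#' @param features descriptor columns to use.
#' @param exclude character vector of compound ids to drop.
#' @param quantitative_only drop censored measurements (default TRUE).
#' @return list with \code{X} (data.frame), \code{y} (ordered factor),
#'   \code{ids}.
#' @export
classification_matrix <- function(dataset,
                                  features = c("tpsa", "brlogd", "log_kw_iam"),
                                  exclude = NULL, quantitative_only = TRUE) {
  stopifnot(inherits(dataset, "protac_dataset"))
  d <- dataset$descriptors
  sol <- dataset$solubility
  miss <- setdiff(features, names(d))
  if (length(miss) > 0) stop("descriptor column(s) not present: ",
                             paste(miss, collapse = ", "))
  keep <- !(d$id %in% exclude)
  m <- match(d$id, sol$compound_id)
  keep <- keep & !is.na(m)
  if (quantitative_only) keep <- keep & !sol$censored[m]
  X <- d[keep, features, drop = FALSE]
  rownames(X) <- NULL
  y <- factor(as.character(sol$gsk_class[m][keep]),
              levels = c("low", "intermediate", "high"), ordered = TRUE)
  list(X = X, y = y, ids = d$id[keep])
}
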