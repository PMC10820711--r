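#' PLS discriminant analysis with venetian-blinds model selection
#'
#' One-hot encodes the class labels into a dummy response block, runs
#' [venetianBlindsCV()] with the misclassification rate as the selection
#' criterion, picks the LV count with [selectNLV()], and fits the final
#' model on all samples.
#'
#' @param X samples x features matrix (raw scale; preprocessing is part of
#'   the model)
#' @param labels class labels, one per row of X (each class needs >= 2
#'   samples)
#' @param maxLV,nSplits cross-validation settings
#' @param xScale X preprocessing: "center" (spectra) or "autoscale"
#'   (volatile tables)
#' @param selectTol parsimony tolerance passed to [selectNLV()]
#' @return list with `model` ([PLSModel-class]) and `cv` ([CVResult-class],
#'   `chosenNLV` filled in)
#' @export
plsdaFit <- function(X, labels, maxLV = 10L, nSplits = 5L,
                     xScale = c("center", "autoscale", "none"),
                     selectTol = 0.02) {
    xScale <- match.arg(xScale)
    f <- droplevels(factor(labels))
    if (nlevels(f) < 2L)
        stop("PLS-DA needs at least 2 classes")
    small <- table(f) < 2L
    if (any(small))
        stop("class(es) with fewer than 2 samples: ",
             paste(names(small)[small], collapse = ", "))
    Y <- dummyMatrix(f)
    cv <- venetianBlindsCV(X, Y, maxLV = maxLV, nSplits = nSplits,
                           xScale = xScale, yScale = "center",
                           responseKind = "class-dummy",
                           classLevels = levels(f))
    nlv <- selectNLV(cv, selectTol)
    cv@chosenNLV <- nlv
    model <- fitPLS(X, Y, nLV = nlv, xScale = xScale, yScale = "center",
                    responseKind = "class-dummy", classLevels = levels(f))
    list(model = model, cv = cv)
}

#' Assign class labels from dummy-response predictions
#'
#' Arg-max over the class columns; exact ties are broken in favour of the
#' earlier class column and flagged in the `ties` attribute.
#'
#' @param predictions samples x classes matrix of predicted memberships
#' @param classLevels class labels (defaults to column names)
#' @return factor of assigned labels with attribute `ties` (row indices of
#'   tied assignments)
#' @export
plsdaAssign <- function(predictions, classLevels = colnames(predictions)) {
    predictions <- as.matrix(predictions)
    if (is.null(classLevels))
        stop("class levels are required (no column names on predictions)")
    idx <- max.col(predictions, ties.method = "first")
    rowMax <- predictions[cbind(seq_len(nrow(predictions)), idx)]
    ties <- which(rowSums(predictions == rowMax) > 1L)
    out <- factor(classLevels[idx], levels = classLevels)
    attr(out, "ties") <- ties
    out
}

#' Classification performance metrics
#'
#' Per-class one-vs-rest sensitivity TP/(TP+FN) and specificity TN/(TN+FP),
#' overall accuracy, classification error (the mean over classes of the
#' balanced error rate `((1 - sens) + (1 - spec)) / 2`), and - when the
#' continuous dummy predictions are supplied - the coefficient of
#' determination of the dummy-response fit.
#'
#' @param truth true class labels
#' @param assigned assigned class labels
#' @param dummyPredictions optional samples x classes matrix of continuous
#'   predicted memberships for the R-squared
#' @return a [ClassMetrics-class]
#' @export
classificationMetrics <- function(truth, assigned, dummyPredictions = NULL) {
    truth <- as.character(truth)
    assigned <- as.character(assigned)
    stopifnot(length(truth) == length(assigned))
    if (!length(intersect(unique(truth), unique(assigned))))
        stop("true and assigned label sets are disjoint")
    lv <- union(unique(truth), unique(assigned))
    conf <- table(truth = factor(truth, lv), assigned = factor(assigned, lv))
    conf <- unclass(conf)
    n <- sum(conf)
    sens <- diag(conf) / rowSums(conf)
    spec <- vapply(seq_along(lv), function(k) {
        tn <- n - sum(conf[k, ]) - sum(conf[, k]) + conf[k, k]
        fp <- sum(conf[, k]) - conf[k, k]
        tn / (tn + fp)
    }, numeric(1L))
    names(spec) <- lv
    acc <- sum(diag(conf)) / n
    err <- mean(((1 - sens) + (1 - spec)) / 2, na.rm = TRUE)
    r2 <- NA_real_
    if (!is.null(dummyPredictions)) {
        P <- as.matrix(dummyPredictions)
        Yd <- dummyMatrix(factor(truth, colnames(P) %||% lv))
        r2 <- 1 - sum((Yd - P)^2) /
            sum(sweep(Yd, 2L, colMeans(Yd))^2)
    }
    new("ClassMetrics", confusion = conf, sensitivity = sens,
        specificity = spec, accuracy = acc, classError = err, r2 = r2)
}

setMethod("show", "ClassMetrics", function(object) {
    cat(sprintf("ClassMetrics: accuracy %.3f, classification error %.3f",
                object@accuracy, object@classError))
    if (!is.na(object@r2)) cat(sprintf(", R2 %.3f", object@r2))
    cat("\n  per-class sensitivity:",
        paste(sprintf("%s %.3f", names(object@sensitivity),
                      object@sensitivity), collapse = ", "), "\n")
    cat("  per-class specificity:",
        paste(sprintf("%s %.3f", names(object@specificity),
                      object@specificity), collapse = ", "), "\n")
})

# Tabular view for writing metric reports.
.classMetricsTable <- function(m) {
    data.frame(class = names(m@sensitivity),
               sensitivity = as.numeric(m@sensitivity),
               specificity = as.numeric(m@specificity),
               accuracy = m@accuracy,
               classError = m@classError,
               r2 = m@r2, row.names = NULL)
}
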