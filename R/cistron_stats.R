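#' Two-factor logistic regression of site polymorphism
#'
#' Models the probability that a reference position is polymorphic (or
#' highly polymorphic) in at least one individual as a function of its
#' region class (subunit vs spacer) and pairing state (paired vs unpaired),
#' with interaction. The reference level is a paired, spacer position; odds
#' ratios below 1 therefore indicate categories that decrease the likelihood
#' of polymorphism. Confidence intervals are Wald (estimate +/- 1.96 SE,
#' exponentiated).
#'
#' @param data data.frame with the binary response column plus
#'   `region_class` (`"subunit"`/`"spacer"`) and `pairing`
#'   (`"paired"`/`"unpaired"`).
#' @param response which response column to model: `any_poly` or `any_high`.
#' @return data.frame of class `site_logistic` with one row per term
#'   (intercept, subunit, unpaired, subunit:unpaired): `estimate`,
#'   `std_error`, `z`, `p`, `odds_ratio`, `ci_lo`, `ci_hi`.
#' @export
fit_site_logistic <- function(data, response = c("any_poly", "any_high")) {
  response <- match.arg(response)
  y <- as.integer(as.logical(data[[response]]))
  if (length(unique(y)) < 2L) {
    stop("response '", response, "' is constant; nothing to model")
  }
  subunit <- factor(data$region_class, levels = c("spacer", "subunit"))
  unpaired <- factor(data$pairing, levels = c("paired", "unpaired"))
  if (nlevels(droplevels(subunit)) < 2L || nlevels(droplevels(unpaired)) < 2L) {
    stop("both levels of each factor must be present")
  }
  if (any(table(subunit, unpaired) == 0L)) {
    warning("empty design cell; interaction estimate is unreliable")
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ subunit * unpaired, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || any(abs(stats::coef(fit)) > 15)) {
    stop("complete (or quasi-complete) separation detected; ",
         "consider exact logistic methods")
  }
  sm <- summary(fit)$coefficients
  term <- c("(Intercept)", "subunit", "unpaired", "subunit:unpaired")
  out <- data.frame(
    term = term,
    estimate = sm[, 1], std_error = sm[, 2], z = sm[, 3], p = sm[, 4],
    odds_ratio = exp(sm[, 1]),
    ci_lo = exp(sm[, 1] - 1.96 * sm[, 2]),
    ci_hi = exp(sm[, 1] + 1.96 * sm[, 2]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("site_logistic", "data.frame")
  out
}

#' Two-way type III ANOVA of square-root polymorphic-individual counts
#'
#' Tests whether the number of individuals polymorphic at a position depends
#' on region class and pairing state, using square-root transformed counts
#' and type III sums of squares (suitable for the unbalanced position
#' design). Factors are coded with sum-to-zero contrasts, as type III
#' requires.
#'
#' @param data data.frame with columns `n_poly_individuals`, `region_class`,
#'   `pairing`.
#' @return data.frame with one row per term (intercept, paired, subunit,
#'   paired:subunit, residuals): `sum_sq`, `df`, `F`, `p`.
#' @export
anova_sqrt_counts <- function(data) {
  y <- sqrt(data$n_poly_individuals)
  paired <- factor(data$pairing, levels = c("paired", "unpaired"))
  subunit <- factor(data$region_class, levels = c("spacer", "subunit"))
  if (nlevels(droplevels(paired)) < 2L || nlevels(droplevels(subunit)) < 2L) {
    stop("both levels of each factor must be present")
  }
  if (any(table(paired, subunit) == 0L)) {
    stop("empty design cell: type III sums of squares are undefined")
  }
  d <- data.frame(y = y, paired = paired, subunit = subunit)
  fit <- stats::lm(y ~ paired * subunit, data = d,
                   contrasts = list(paired = "contr.sum",
                                    subunit = "contr.sum"))
  a3 <- tryCatch(car::Anova(fit, type = 3), error = function(e) NULL)
  if (is.null(a3)) {
    # perfect fit (zero residual SS): compute the type III decomposition
    # directly as drop-one RSS differences on the sum-to-zero design
    X <- stats::model.matrix(fit)
    assign <- attr(X, "assign")
    rss <- function(cols) {
      sum(stats::lm.fit(X[, cols, drop = FALSE], d$y)$residuals^2)
    }
    rss_full <- rss(seq_len(ncol(X)))
    ss <- vapply(0:3, function(t) rss(which(assign != t)) - rss_full,
                 numeric(1))
    a3 <- data.frame(`Sum Sq` = c(ss, rss_full),
                     Df = c(rep(1L, 4L), nrow(d) - 4L),
                     `F value` = NA_real_, `Pr(>F)` = NA_real_,
                     check.names = FALSE)
  }
  out <- data.frame(
    term = c("(Intercept)", "paired", "subunit", "paired:subunit",
             "residuals"),
    sum_sq = a3[["Sum Sq"]], df = a3[["Df"]], F = a3[["F value"]],
    p = a3[["Pr(>F)"]], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize a sample polymorphism table
#'
#' Arithmetic summaries (mean, min, max, and which sample attains the
#' extremes) for every numeric column of a per-sample polymorphism table,
#' e.g. the polymorphic and highly polymorphic site counts and percentages
#' across all sequenced individuals. The mean is reported both raw and
#' rounded to the precision at which such tables are usually printed
#' (integers for counts, two decimals for percentages).
#'
#' @param tab data.frame with one label column (the first non-numeric
#'   column) and numeric summary columns.
#' @return data.frame with one row per numeric column: `column`, `mean`,
#'   `mean_rounded`, `min`, `max`, `argmin`, `argmax`.
#' @examples
#' t1 <- read_table1()
#' summarize_samples(t1)
#' @export
summarize_samples <- function(tab) {
  stopifnot(nrow(tab) > 0L)
  num <- vapply(tab, is.numeric, logical(1))
  label_col <- names(tab)[!num][1]
  labels <- if (is.na(label_col)) as.character(seq_len(nrow(tab))) else
    tab[[label_col]]
  do.call(rbind, lapply(names(tab)[num], function(cn) {
    x <- tab[[cn]]
    integral <- all(abs(x - round(x)) < 1e-9)
    data.frame(column = cn,
               mean = mean(x),
               mean_rounded = round(mean(x), if (integral) 0L else 2L),
               min = min(x), max = max(x),
               argmin = labels[which.min(x)],
               argmax = labels[which.max(x)],
               stringsAsFactors = FALSE)
  }))
}

#' Load the shipped per-sample polymorphism table
#'
#' Returns the package's transcription of a published polymorphic-site
#' abundance table for 125 milkweed nrDNA samples: per sample, the number
#' and percentage of polymorphic (>= 2% differing reads) and highly
#' polymorphic (>= 10%) positions.
#'
#' @param path path to the TSV (defaults to the copy shipped with the
#'   package).
#' @return data.frame with columns `taxon`, `voucher`, `poly_n`, `poly_pct`,
#'   `high_n`, `high_pct`, `sra`.
#' @export
read_table1 <- function(path = system.file("extdata", "table1.tsv",
                                           package = "copyvar")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
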