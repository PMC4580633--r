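# Feeding-prediction models: term DSL, design-matrix construction with
# the transforms the models use (natural log, quadratic, two-way
# interaction, summer dummy), maximum-likelihood binomial-logit fitting,
# small-sample AICc and Akaike-weight model selection.

#' Model specification
#'
#' A model is an ordered list of term strings over the covariate names;
#' the intercept is always included. Supported forms:
#'
#' * `"NAME"` - main effect of a covariate column;
#' * `"log(NAME)"` - natural-log transform;
#' * `"NAME^2"` - quadratic of the raw covariate (requires the main
#'   effect to be present);
#' * `"A:B"` - two-way interaction (elementwise product; both parents,
#'   each a main or log term, must be present);
#' * `"SUM"` - the summer-season dummy, 1 when `SEAS == "SUM"`.
#'
#' @param ... term strings (character vectors are flattened).
#' @param label optional display label.
#' @return object of class `model_spec`.
#' @examples
#' model_spec("CENTER", "CENTER^2", "log(POSCOUNT)", "NIGHTPROP",
#'            "log(POSCOUNT):NIGHTPROP")
#' @export
model_spec <- function(..., label = NULL) {
  terms <- as.character(unlist(list(...)))
  if (anyDuplicated(terms)) stop_kc("duplicate terms in model spec")
  parsed <- lapply(terms, parse_term)
  # hierarchy: quadratics need their main effect, interactions need
  # both parents present as terms
  have <- terms
  for (p in parsed) {
    if (p$kind == "quad" && !(p$var %in% have)) {
      stop_kc("quadratic term ", p$term, " requires main effect ", p$var)
    }
    if (p$kind == "interact" &&
        !all(c(p$parent1, p$parent2) %in% have)) {
      stop_kc("interaction ", p$term,
              " requires both parent terms to be present")
    }
  }
  structure(list(terms = terms, parsed = parsed,
                 label = label %||% paste(terms, collapse = " + ")),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> FEEDING ~ 1",
      if (length(x$terms)) paste("+", paste(x$terms, collapse = " + ")),
      "\n")
  invisible(x)
}

parse_term <- function(term) {
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop_kc("bad interaction term: ", term)
    return(list(kind = "interact", term = term,
                parent1 = parts[1], parent2 = parts[2]))
  }
  if (grepl("\\^2$", term)) {
    return(list(kind = "quad", term = term, var = sub("\\^2$", "", term)))
  }
  if (grepl("^log\\(.*\\)$", term)) {
    return(list(kind = "log", term = term,
                var = sub("^log\\((.*)\\)$", "\\1", term)))
  }
  list(kind = "main", term = term, var = term)
}

term_vars <- function(spec) {
  unique(unlist(lapply(spec$parsed, function(p) {
    switch(p$kind,
      interact = c(base_var(p$parent1), base_var(p$parent2)),
      base_var(p$term)
    )
  })))
}

base_var <- function(term) {
  p <- parse_term(term)
  if (p$kind == "interact") stop_kc("nested interaction not supported")
  if (p$term == "SUM") "SEAS" else p$var
}

eval_simple_term <- function(term, data) {
  p <- parse_term(term)
  col <- function(v) {
    if (v == "SUM") {
      return(as.numeric(toupper(as.character(data$SEAS)) == "SUM"))
    }
    if (is.null(data[[v]])) stop_kc("missing covariate: ", v)
    as.numeric(data[[v]])
  }
  switch(p$kind,
    main = col(p$term),
    quad = col(p$var)^2,
    log = {
      v <- col(p$var)
      bad <- which(v <= 0)
      if (length(bad)) {
        stop_kc(sprintf("log of non-positive %s at row(s) %s",
                        p$var, paste(head(bad, 5), collapse = ", ")))
      }
      log(v)
    },
    interact = eval_simple_term(p$parent1, data) *
      eval_simple_term(p$parent2, data)
  )
}

#' Build a design matrix from a covariate table
#'
#' Columns follow spec order after the leading intercept; rows with a
#' missing value in any covariate the spec references are dropped with a
#' reported count.
#'
#' @param data covariate data.frame (e.g. from [cluster_covariates()] or
#'   [read_cluster_table()]).
#' @param spec a [model_spec()].
#' @param response name of the response column (default "FEEDING");
#'   `NULL` for prediction-only matrices.
#' @return list with `X` (matrix incl. `(Intercept)` column), `y`
#'   (integer response or `NULL`), `rows` (indices of retained rows),
#'   `n_dropped`.
#' @export
build_design_matrix <- function(data, spec, response = "FEEDING") {
  vars <- term_vars(spec)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop_kc("missing covariate(s): ", paste(missing_vars, collapse = ", "))
  }
  need <- data[, vars, drop = FALSE]
  need_num <- need
  if ("SEAS" %in% vars) need_num$SEAS <- as.character(need$SEAS)
  keep <- complete.cases(need_num)
  if (!is.null(response)) {
    if (is.null(data[[response]])) {
      stop_kc("missing response column: ", response)
    }
    keep <- keep & !is.na(data[[response]])
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped for missing covariates")
  }
  d <- data[keep, , drop = FALSE]
  cols <- lapply(spec$terms, eval_simple_term, data = d)
  X <- cbind(`(Intercept)` = rep(1, nrow(d)),
             do.call(cbind, c(cols, list(deparse.level = 0))))
  if (length(spec$terms)) colnames(X) <- c("(Intercept)", spec$terms)
  y <- if (!is.null(response)) as.integer(d[[response]]) else NULL
  list(X = X, y = y, rows = which(keep), n_dropped = n_dropped)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1).
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations (must exceed k + 1).
#' @return numeric AICc.
#' @examples
#' aicc(0, 1, 100)  # 2 + 4/98
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop_kc("AICc undefined: need n > k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a binomial-logit model by maximum likelihood
#'
#' IRLS fit of the binomial log-likelihood with logit link. Errors on
#' rank deficiency (naming the collinear columns), on apparent complete
#' separation (any standardized coefficient magnitude above 50), and on
#' non-convergence within 100 iterations.
#'
#' @param y 0/1 response vector.
#' @param X design matrix including the intercept column (e.g. from
#'   [build_design_matrix()]).
#' @param spec optional [model_spec()] stored with the fit.
#' @return object of class `kc_fit`: list with `beta`, `vcov`, `logLik`,
#'   `k`, `n`, `aicc`, `converged`, `spec`.
#' @export
fit_logistic <- function(y, X, spec = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) stop_kc("need more observations than parameters")
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop_kc("design matrix rank-deficient; collinear column(s): ",
            paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(maxit = 100, epsilon = 1e-10))
  )
  if (!fit$converged) stop_kc("IRLS did not converge in 100 iterations")
  beta <- fit$coefficients
  eta <- drop(X %*% beta)
  p <- invlogit(eta)
  ll <- sum(dbinom(y, 1, p, log = TRUE))
  # Separation guard. Coefficients are non-standardized, so divergence
  # is judged on the standardized scale (|beta|*sd > 50) - but only when
  # the likelihood is near-saturated or the classes are perfectly split
  # by the linear predictor: collinear term pairs (e.g. a covariate with
  # its quadratic on a narrow range) legitimately produce large
  # offsetting coefficients at a finite, converged ML optimum.
  sds <- apply(X, 2, sd)
  std <- ifelse(sds > 0, abs(beta) * sds, abs(beta) / 50)
  split_classes <- any(y == 1) && any(y == 0) &&
    min(eta[y == 1]) > max(eta[y == 0])
  if ((split_classes && ll > -1e-4) ||
      (any(std > 50) && ll > -1e-3 * n)) {
    bad <- if (any(std > 50)) {
      paste0(" (diverging coefficients: ",
             paste(colnames(X)[std > 50], collapse = ", "), ")")
    } else {
      " (classes perfectly separated)"
    }
    stop_kc("apparent complete separation", bad)
  }
  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  vc <- chol2inv(chol(info))
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(spec = spec, beta = beta, vcov = vc, logLik = ll, k = k, n = n,
         aicc = aicc(ll, k, n), converged = TRUE,
         fitted = p, terms = colnames(X)),
    class = "kc_fit"
  )
}

#' @export
print.kc_fit <- function(x, ...) {
  cat("<kc_fit> ", if (!is.null(x$spec)) x$spec$label else "",
      "\n  k = ", x$k, ", n = ", x$n,
      ", logLik = ", format(x$logLik, digits = 6),
      ", AICc = ", format(x$aicc, digits = 6), "\n", sep = "")
  print(round(x$beta, 5))
  invisible(x)
}

#' Fit a model spec to a covariate table
#'
#' Convenience wrapper: [build_design_matrix()] then [fit_logistic()].
#'
#' @inheritParams build_design_matrix
#' @return a `kc_fit` (see [fit_logistic()]).
#' @export
fit_model <- function(data, spec, response = "FEEDING") {
  dm <- build_design_matrix(data, spec, response = response)
  fit_logistic(dm$y, dm$X, spec = spec)
}

# The four covariate grouping components of the top model.
component_groups <- function() {
  list(
    SpTemp = c("CENTER", "CENTER^2", "log(POSCOUNT)", "NIGHTPROP",
               "log(POSCOUNT):NIGHTPROP"),
    Acvty = c("ACCX", "ACCX^2", "ACCXYDIFF"),
    GrndTru = c("SEARCH_LAG", "FIELDPROP", "FIELDPROP^2"),
    Seas = "SUM"
  )
}

#' The top feeding-prediction model specification
#'
#' Spatio-temporal terms (CENTER, CENTER^2, log POSCOUNT, NIGHTPROP,
#' log POSCOUNT x NIGHTPROP), activity terms (ACCX, ACCX^2, ACCXYDIFF),
#' the cross-group interactions ACCX x CENTER and ACCXYDIFF x
#' log POSCOUNT, ground-truthing error terms (SEARCH_LAG, FIELDPROP,
#' FIELDPROP^2) and the summer dummy: 15 parameters with the intercept.
#'
#' @return a [model_spec()].
#' @export
top_model_spec <- function() {
  g <- component_groups()
  model_spec(g$SpTemp, g$Acvty, "ACCX:CENTER", "ACCXYDIFF:log(POSCOUNT)",
             g$GrndTru, g$Seas,
             label = "SpTemp+Acvty+GrndTru+Seas")
}

#' The 16 component candidate models
#'
#' All 2^4 on/off combinations of the four covariate grouping components
#' (SpTemp, Acvty, GrndTru, Seas). The cross-group interactions
#' ACCX x CENTER and ACCXYDIFF x log(POSCOUNT) are included only when
#' both parent groups (SpTemp and Acvty) are on. Includes the
#' intercept-only (null) model.
#'
#' @return named list of 16 [model_spec()] objects.
#' @export
component_candidate_set <- function() {
  g <- component_groups()
  out <- list()
  for (sp in c(TRUE, FALSE)) for (ac in c(TRUE, FALSE)) {
    for (gt in c(TRUE, FALSE)) for (se in c(TRUE, FALSE)) {
      terms <- c(
        if (sp) g$SpTemp,
        if (ac) g$Acvty,
        if (sp && ac) c("ACCX:CENTER", "ACCXYDIFF:log(POSCOUNT)"),
        if (gt) g$GrndTru,
        if (se) g$Seas
      )
      label <- paste(c(if (sp) "SpTemp", if (ac) "Acvty",
                       if (gt) "GrndTru", if (se) "Seas"),
                     collapse = "+")
      if (label == "") label <- "Null"
      out[[label]] <- model_spec(terms, label = label)
    }
  }
  out
}

#' AICc model selection over a set of specs
#'
#' All specs are fitted to one common observation set: rows missing any
#' covariate used by any spec in the set are dropped globally first, so
#' every AICc shares the same n (information criteria are only
#' comparable on identical data). Reports delta AICc relative to the
#' minimum and Akaike weights w_i = exp(-delta_i/2) / sum_j
#' exp(-delta_j/2).
#'
#' @param specs list of [model_spec()] (e.g.
#'   [component_candidate_set()]).
#' @param data covariate data.frame with the response column.
#' @param response response column name (default "FEEDING").
#' @return object of class `kc_selection`: a data.frame (model, k,
#'   logLik, AICc, delta, weight) sorted by AICc, with the fitted models
#'   in `attr(, "fits")` and the common observation set rows in
#'   `attr(, "rows")`.
#' @export
select_models <- function(specs, data, response = "FEEDING") {
  if (!length(specs)) stop_kc("need at least one spec")
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$label, "")
  }
  all_vars <- unique(unlist(lapply(specs, term_vars)))
  need <- data[, intersect(all_vars, names(data)), drop = FALSE]
  if ("SEAS" %in% names(need)) need$SEAS <- as.character(need$SEAS)
  keep <- complete.cases(need) & !is.na(data[[response]])
  if (any(!keep)) {
    message(sum(!keep),
            " row(s) dropped listwise for the model comparison")
  }
  d <- data[keep, , drop = FALSE]
  fits <- lapply(seq_along(specs), function(i) {
    tryCatch(fit_model(d, specs[[i]], response = response),
             error = function(e) {
               stop_kc("fit failed for model '", names(specs)[i], "': ",
                       conditionMessage(e))
             })
  })
  names(fits) <- names(specs)
  tab <- data.frame(
    model = names(specs),
    k = vapply(fits, `[[`, 0, "k"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    AICc = vapply(fits, `[[`, 0, "aicc"),
    stringsAsFactors = FALSE
  )
  tab$delta <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  ord <- order(tab$AICc)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], rows = which(keep),
            class = c("kc_selection", "data.frame"))
}
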