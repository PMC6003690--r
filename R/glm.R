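## Repeated-measures GLM of subtype fingerprints on age and gender.
## The omnibus test treats the analysis parameters as a multivariate
## response with subtype as a within-subject factor: between-subject terms
## (age, gender) are tested on subject-mean responses, within-subject terms
## (type and its interactions) on subtype difference contrasts, each by
## Wilks' lambda with the exact F transform for single-df hypotheses.

## Wilks test of L B = 0 in the multivariate linear model Y = X B + E,
## for a single-row L (exact F).
wilksRow <- function(Y, X, L) {
  n <- nrow(Y); m <- ncol(Y); r <- qr(X)$rank
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  Res <- Y - X %*% B
  E <- crossprod(Res)
  lb <- L %*% B                              # 1 x m
  H <- crossprod(lb, lb) / drop(L %*% XtXi %*% t(L))
  lam <- det(E) / det(E + H)
  dfe <- n - r
  df2 <- dfe - m + 1
  if (df2 < 1) stop("fewer subjects than model degrees of freedom")
  Fv <- (1 - lam) / lam * df2 / m
  c(F = Fv, df1 = m, df2 = df2, p = stats::pf(Fv, m, df2, lower.tail = FALSE))
}

#' Repeated-measures GLM of fingerprints on subtype, age and gender
#'
#' Fits (a) an omnibus multivariate model over the analysis parameters with
#' subtype as within-subject factor and age (continuous) plus gender
#' (binary) as between-subject covariates, testing Age, Gender, Type,
#' Type x Age and Type x Gender by Wilks' lambda, and (b) per-parameter
#' univariate repeated-measures models (aov with a subject error stratum)
#' with the same terms. Casewise deletion is applied per analysis; degrees
#' of freedom accompany every F.
#'
#' @param tab fingerprint table from [extractFingerprintTable()] including
#'   `age` and `gender` columns.
#' @param params parameter columns for the omnibus (default: the columns
#'   present among the seven analysis parameters).
#' @param alpha display threshold recorded with the result.
#' @return list: `omnibus` (data.frame term/F/df1/df2/p), `perParameter`
#'   (data.frame param/term/F/df1/df2/p), `n` (complete subjects for the
#'   omnibus).
#' @export
glmSubtypeAgeGender <- function(tab, params = NULL, alpha = 0.05) {
  stopifnot(all(c("age", "gender") %in% colnames(tab)))
  analysis <- c("R1", "R2", "AD", "RD", "chi_m", "R2star", "MPF")
  params <- params %||% intersect(analysis, colnames(tab))
  tab <- tab[tab$subtype != "GM", , drop = FALSE]
  subtypes <- sort(unique(tab$subtype))
  S <- length(subtypes)
  if (S < 2L) stop("need at least two subtypes")
  subs <- sort(unique(tab$subject))
  ## wide array: subject x subtype x param
  arr <- array(NA_real_, c(length(subs), S, length(params)),
               dimnames = list(subs, subtypes, params))
  for (i in seq_len(nrow(tab))) {
    arr[tab$subject[i], tab$subtype[i], ] <-
      unlist(tab[i, params], use.names = FALSE)
  }
  cov <- unique(tab[, c("subject", "age", "gender")])
  cov <- cov[match(subs, cov$subject), ]
  complete <- apply(is.finite(arr), 1, all) &
    is.finite(cov$age) & !is.na(cov$gender)
  n <- sum(complete)
  A <- arr[complete, , , drop = FALSE]
  X <- stats::model.matrix(~ age + gender,
                           data.frame(age = cov$age[complete],
                                      gender = factor(cov$gender[complete])))
  ## between-subject responses: subject means over subtypes
  M <- apply(A, c(1, 3), mean)
  ## within-subject responses: Helmert contrasts over subtypes, per param
  Cm <- stats::contr.helmert(S)
  D <- matrix(NA_real_, n, (S - 1) * length(params))
  k <- 0L
  for (p in seq_along(params)) for (j in seq_len(S - 1)) {
    k <- k + 1L
    D[, k] <- A[, , p] %*% Cm[, j]
  }
  omn <- rbind(
    Age = wilksRow(M, X, t(c(0, 1, 0))),
    Gender = wilksRow(M, X, t(c(0, 0, 1))),
    Type = wilksRow(D, X, t(c(1, 0, 0))),
    `Type x Age` = wilksRow(D, X, t(c(0, 1, 0))),
    `Type x Gender` = wilksRow(D, X, t(c(0, 0, 1))))
  omnibus <- data.frame(term = rownames(omn), omn, row.names = NULL)
  ## per-parameter univariate repeated measures
  per <- list()
  allp <- setdiff(colnames(tab),
                  c("subject", "subtype", "age", "gender"))
  for (p in allp) {
    sub <- tab[, c("subject", "subtype", "age", "gender", p)]
    names(sub)[5] <- "y"
    wide <- stats::reshape(sub, idvar = "subject", timevar = "subtype",
                           direction = "wide")
    ok <- stats::complete.cases(wide)
    keep <- wide$subject[ok]
    sub <- sub[sub$subject %in% keep & is.finite(sub$y), , drop = FALSE]
    np <- length(unique(sub$subject))
    if (np < 5L) next
    sub$subject <- factor(sub$subject)
    sub$subtype <- factor(sub$subtype)
    sub$gender <- factor(sub$gender)
    fit <- stats::aov(y ~ subtype * age + subtype * gender +
                        Error(subject), data = sub)
    sm <- summary(fit)
    for (stratum in sm) {
      tb <- stratum[[1]]
      terms <- trimws(rownames(tb))
      for (tm in setdiff(terms, "Residuals")) {
        i <- which(terms == tm)
        ri <- which(terms == "Residuals")
        per[[length(per) + 1L]] <- data.frame(
          param = p,
          term = c(age = "Age", gender = "Gender", subtype = "Type",
                   `subtype:age` = "Type x Age",
                   `subtype:gender` = "Type x Gender")[tm],
          F = tb$`F value`[i], df1 = tb$Df[i], df2 = tb$Df[ri],
          p = tb$`Pr(>F)`[i])
      }
    }
  }
  list(omnibus = omnibus,
       perParameter = do.call(rbind, per),
       n = n, alpha = alpha)
}
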