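# The five design-matrix families. Every representation is a pure
# column-projection/concatenation of the feature and SPI tensors: no value
# in a design matrix differs from its tensor source.

new_design_matrix <- function(X, kind, unit_id = "") {
  stopifnot(is.matrix(X), !is.null(colnames(X)),
            !anyDuplicated(colnames(X)))
  structure(list(X = X, column_names = colnames(X), kind = kind,
                 unit_id = unit_id), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> kind = %s%s, %d x %d\n", x$kind,
              if (nzchar(x$unit_id)) paste0(" (", x$unit_id, ")") else "",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Per-region representation: all features of a single region
#'
#' One model per brain region: an N x F matrix of that region's 25
#' dynamical features across participants.
#'
#' @param features a \code{feature_tensor}.
#' @param region region label (or index).
#' @return a \code{design_matrix} of kind \code{"region"} with F = 25
#'   columns.
#' @export
build_region <- function(features, region) {
  dn <- dimnames(features$values)
  r <- if (is.character(region)) match(region, dn[[2]]) else region
  if (is.na(r) || r < 1 || r > length(dn[[2]]))
    stop("unknown region: ", region)
  X <- features$values[, r, , drop = TRUE]
  X <- matrix(X, nrow = dim(features$values)[1],
              dimnames = list(dn[[1]], dn[[3]]))
  new_design_matrix(X, "region", unit_id = dn[[2]][r])
}

#' Per-feature representation: one feature's brain-wide map
#'
#' One model per time-series feature: an N x R matrix of that feature's
#' value in every region.
#'
#' @param features a \code{feature_tensor}.
#' @param feature feature name (or index), one of
#'   \code{\link{feature_names}}.
#' @return a \code{design_matrix} of kind \code{"feature"} with R columns.
#' @export
build_feature <- function(features, feature) {
  dn <- dimnames(features$values)
  f <- if (is.character(feature)) match(feature, dn[[3]]) else feature
  if (is.na(f) || f < 1 || f > length(dn[[3]]))
    stop("unknown feature: ", feature)
  X <- features$values[, , f, drop = TRUE]
  X <- matrix(X, nrow = dim(features$values)[1],
              dimnames = list(dn[[1]], dn[[2]]))
  new_design_matrix(X, "feature", unit_id = dn[[3]][f])
}

#' Combined univariate representation: all features x all regions
#'
#' Concatenates every intra-regional feature from the whole brain into a
#' single N x (R*F) matrix; column order is region-major
#' (region1_feature1, region1_feature2, ...).
#'
#' @param features a \code{feature_tensor}.
#' @return a \code{design_matrix} of kind \code{"uni_combo"}.
#' @export
build_uni_combo <- function(features) {
  dn <- dimnames(features$values)
  N <- dim(features$values)[1]; R <- length(dn[[2]]); F <- length(dn[[3]])
  X <- matrix(NA_real_, N, R * F)
  cn <- character(R * F)
  for (r in seq_len(R)) {
    idx <- ((r - 1) * F + 1):(r * F)
    X[, idx] <- features$values[, r, ]
    cn[idx] <- paste(dn[[2]][r], dn[[3]], sep = "|")
  }
  dimnames(X) <- list(dn[[1]], cn)
  new_design_matrix(X, "uni_combo")
}

#' Functional-connectivity representation for one SPI
#'
#' @param spis a \code{spi_tensor}.
#' @param spi SPI name.
#' @return a \code{design_matrix} of kind \code{"fc"} with P columns
#'   (P depends on the SPI's directedness).
#' @export
build_fc <- function(spis, spi) {
  if (!spi %in% names(spis)) stop("unknown SPI: ", spi)
  new_design_matrix(spis[[spi]]$values, "fc", unit_id = spi)
}

#' Coupling-plus-local representation for one SPI
#'
#' Concatenates one SPI's coupling matrix (FC block first) with the full
#' region x feature matrix.
#'
#' @param spis a \code{spi_tensor}.
#' @param spi SPI name.
#' @param features a \code{feature_tensor} over the same participants.
#' @return a \code{design_matrix} of kind \code{"fc_combo"} with
#'   P + R*F columns.
#' @export
build_fc_combo <- function(spis, spi, features) {
  fc <- build_fc(spis, spi)
  uc <- build_uni_combo(features)
  if (!identical(rownames(fc$X), rownames(uc$X)))
    stop("SPI and feature tensors cover different participants")
  X <- cbind(fc$X, uc$X)
  new_design_matrix(X, "fc_combo", unit_id = spi)
}

#' Covariate-only design matrix (age, sex)
#'
#' Demographic baseline: sex encoded male = 0, female = 1.
#'
#' @param meta participant metadata data.frame (with
#'   \code{participant_id}, \code{age}, \code{sex}).
#' @param columns subset of \code{c("age", "sex")}.
#' @return a \code{design_matrix} of kind \code{"covariate"}.
#' @export
build_covariates <- function(meta, columns = c("age", "sex")) {
  columns <- match.arg(columns, c("age", "sex"), several.ok = TRUE)
  X <- as.matrix(meta[, columns, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- meta$participant_id
  new_design_matrix(X, "covariate", unit_id = paste(columns, collapse = "+"))
}

#' Append covariate columns to an existing design matrix
#' @param dm a \code{design_matrix}.
#' @param cov a covariate \code{design_matrix} over the same participants.
#' @return a \code{design_matrix} with d + ncol(cov) columns.
#' @export
augment_with_covariates <- function(dm, cov) {
  stopifnot(nrow(dm$X) == nrow(cov$X))
  new_design_matrix(cbind(dm$X, cov$X), dm$kind, dm$unit_id)
}
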