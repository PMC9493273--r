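#' Genomic relationship matrix from marker codes
#'
#' Builds the marker-derived relationship matrix G = X_c X_c' / p among
#' lines, where X_c is the 0/1/2 dosage matrix after imputation, centering
#' and (optionally) per-marker scaling.  Under centering + scaling the
#' diagonal averages approximately 1, the usual GBLUP convention.
#'
#' @param markers a `marker_matrix` (lines x p, codes 0/1/2, `NA` allowed).
#' @param impute missing-code policy: `"mean"` replaces missing cells with
#'   the marker mean, `"error"` refuses missing data.
#' @param center center each marker column at its mean (default `TRUE`).
#' @param scale divide each centered column by its standard deviation
#'   (default `TRUE`); monomorphic markers (zero variance) are dropped
#'   when scaling, and must not be the whole panel.
#' @return symmetric positive semidefinite matrix with line IDs as
#'   dimnames.
#' @export
genomic_relationship <- function(markers,
                                 impute = c("mean", "error"),
                                 center = TRUE,
                                 scale = TRUE) {
  impute <- match.arg(impute)
  X <- unclass(markers)
  if (anyNA(X)) {
    if (impute == "error") stop("marker matrix contains missing codes",
                                call. = FALSE)
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  if (center) X <- sweep(X, 2L, colMeans(X), "-")
  if (scale) {
    sdv <- apply(X, 2L, stats::sd)
    poly <- sdv > .Machine$double.eps^0.5
    if (!any(poly)) {
      stop("all markers are monomorphic; cannot build a relationship matrix",
           call. = FALSE)
    }
    X <- sweep(X[, poly, drop = FALSE], 2L, sdv[poly], "/")
  }
  G <- tcrossprod(X) / ncol(X)
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(markers), rownames(markers))
  G
}

#' Expand an entity-level kernel to the record level
#'
#' Computes Z K Z', mapping a covariance among factor levels (e.g. the
#' genomic relationship among lines) onto the phenotype records through the
#' incidence matrix Z.
#'
#' @param kernel square symmetric matrix with level labels as dimnames.
#' @param Z incidence matrix from [incidence()]; its column names must
#'   match the kernel labels.
#' @return records x records symmetric matrix.
#' @export
expand_to_records <- function(kernel, Z) {
  labs <- colnames(Z)
  if (is.null(rownames(kernel)) || !all(labs %in% rownames(kernel))) {
    stop("kernel labels do not cover the incidence matrix columns",
         call. = FALSE)
  }
  K <- kernel[labs, labs, drop = FALSE]
  out <- Z %*% K %*% t(Z)
  (out + t(out)) / 2
}

#' Hadamard (cell-by-cell) product of two kernels
#'
#' The covariance structure of marker-by-environment and marker-by-soil
#' interactions: the elementwise product of a genomic kernel and a factor
#' incidence kernel.  By the Schur product theorem the result of two PSD
#' inputs is PSD.
#'
#' @param A,B square matrices of identical dimension and record ordering.
#' @return their elementwise product.
#' @export
hadamard <- function(A, B) {
  if (!all(dim(A) == dim(B))) {
    stop("Hadamard product requires matrices of identical dimension",
         call. = FALSE)
  }
  A * B
}

#' Check kernel symmetry and positive semidefiniteness
#'
#' @param K square matrix.
#' @param sym_tol maximum tolerated asymmetry.
#' @param psd_tol smallest eigenvalue must be >= -psd_tol * largest.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
check_kernel <- function(K, sym_tol = 1e-10, psd_tol = 1e-8) {
  if (max(abs(K - t(K))) > sym_tol) stop("kernel is not symmetric",
                                         call. = FALSE)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -psd_tol * max(abs(ev), 1)) {
    stop("kernel is not positive semidefinite within tolerance",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Record-level covariance kernels for one model
#'
#' Builds the named set of record-level covariance structures for the four
#' models:
#' \describe{
#'   \item{M1}{environment + line + genomic main effects (E, L, G)}
#'   \item{M2}{M1 plus the marker-by-environment interaction GxE}
#'   \item{M3}{M2 plus soil main effect S and marker-by-soil interaction
#'     GxS}
#'   \item{M4}{M3 without GxE}
#' }
#' The main-effect kernels are Z_E Z_E', Z_L Z_L', Z_S Z_S' and
#' Z_L G Z_L'; the interactions are Hadamard products
#' (Z_L G Z_L') # (Z_E Z_E') and (Z_L G Z_L') # (Z_S Z_S').
#'
#' @param model one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param table a `trial_table` aligned with `G`.
#' @param G line-level genomic relationship matrix covering every line in
#'   `table`.
#' @param normalize if `TRUE`, divide every kernel by its mean diagonal
#'   (off by default; the literal structures are kept).
#' @return list of class `kernel_set` with elements `model`, `n`, and
#'   `kernels` (named list of records x records matrices).
#' @export
model_kernels <- function(model, table, G, normalize = FALSE) {
  model <- match.arg(model, c("M1", "M2", "M3", "M4"))
  ZE <- incidence(table, "environment")
  ZL <- incidence(table, "line")
  KE <- tcrossprod(ZE)
  KL <- tcrossprod(ZL)
  KG <- expand_to_records(G, ZL)
  kernels <- list(E = KE, L = KL, G = KG)
  if (model %in% c("M3", "M4")) {
    ZS <- incidence(table, "soil")
    kernels$S <- tcrossprod(ZS)
  }
  if (model %in% c("M2", "M3")) kernels$GxE <- hadamard(KG, KE)
  if (model %in% c("M3", "M4")) kernels$GxS <- hadamard(KG, kernels$S)
  order <- switch(model,
                  M1 = c("E", "L", "G"),
                  M2 = c("E", "L", "G", "GxE"),
                  M3 = c("E", "L", "S", "G", "GxE", "GxS"),
                  M4 = c("E", "L", "S", "G", "GxS"))
  kernels <- kernels[order]
  if (normalize) {
    kernels <- lapply(kernels, function(K) K / mean(diag(K)))
  }
  structure(list(model = model, n = nrow(table), kernels = kernels),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat("Kernel set for model ", x$model, ": ",
      paste(names(x$kernels), collapse = " + "),
      " (", x$n, " records)\n", sep = "")
  invisible(x)
}
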