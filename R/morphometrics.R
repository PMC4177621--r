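# morphometrics: generalized Procrustes alignment of 3D facial landmark
# configurations, centroid size, tangent-space shape PCs and the all-pairs
# inter-landmark distance scan. Rotations are proper (no reflections):
# faces are chirality-bearing.

#' Construct a landmark set
#'
#' @param coords N x L x 3 array of 3D landmark coordinates (individuals x
#'   landmarks x dimensions)
#' @param sample_ids,landmark_ids identifiers (default from dimnames)
#' @return object of class `landmark_set`
#' @export
landmark_set <- function(coords, sample_ids = dimnames(coords)[[1]],
                         landmark_ids = dimnames(coords)[[2]]) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] < 3) stop_config("need at least 3 landmarks")
  if (anyNA(coords)) stop_config("missing landmarks are not allowed")
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%04d", seq_len(dim(coords)[1]))
  if (is.null(landmark_ids)) landmark_ids <- sprintf("lm%02d", seq_len(dim(coords)[2]))
  dimnames(coords) <- list(sample_ids, landmark_ids, c("x", "y", "z"))
  structure(coords, class = c("landmark_set", "array"))
}

#' Centroid size of each configuration
#'
#' Root sum of squared distances of the landmarks to their centroid, in the
#' configuration's original units.
#'
#' @param landmarks a [landmark_set()]
#' @return numeric vector, one per configuration
#' @export
centroid_size <- function(landmarks) {
  apply(unclass(landmarks), 1, function(m) {
    sqrt(sum(sweep(m, 2, colMeans(m))^2))
  })
}

# proper rotation R minimizing ||X R - Y||_F (Kabsch; no reflections)
.opa_rotate <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalized Procrustes analysis
#'
#' Removes translation (centroid to origin), scales every configuration to
#' unit centroid size (full Procrustes), then iteratively rotates each
#' configuration onto the evolving mean shape (proper rotations only)
#' until the mean shape moves less than `tol`. The GPA objective -- the sum
#' of squared distances to the mean shape -- is non-increasing across
#' iterations.
#'
#' @param landmarks a [landmark_set()]
#' @param tol convergence tolerance on the root mean-shape change
#' @param max_iter iteration cap
#' @return list: `aligned` (a [landmark_set()] of dimensionless shape
#'   coordinates), `mean_shape` (L x 3), `centroid_sizes` (original
#'   units), `n_iter`, `objective` (per-iteration sum of squared
#'   deviations from the mean)
#' @export
gpa <- function(landmarks, tol = 1e-8, max_iter = 100L) {
  A <- unclass(landmarks)
  N <- dim(A)[1]
  if (N < 2) stop_config("GPA needs at least 2 configurations")
  cs <- centroid_size(landmarks)
  if (any(cs < 1e-12)) stop_config("degenerate configuration (all landmarks coincident)")
  for (i in seq_len(N)) {
    m <- A[i, , ]
    m <- sweep(m, 2, colMeans(m))
    A[i, , ] <- m / cs[i]
  }
  mean_shape <- apply(A, c(2, 3), mean)
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(N)) {
      A[i, , ] <- A[i, , ] %*% .opa_rotate(A[i, , ], mean_shape)
    }
    new_mean <- apply(A, c(2, 3), mean)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    obj <- c(obj, sum(vapply(seq_len(N), function(i)
      sum((A[i, , ] - new_mean)^2), numeric(1))))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  list(aligned = landmark_set(A, dimnames(A)[[1]], dimnames(A)[[2]]),
       mean_shape = mean_shape, centroid_sizes = cs, n_iter = it,
       objective = obj)
}

#' Procrustes distance between two aligned configurations
#'
#' @param a,b L x 3 matrices of shape coordinates
#' @return root sum of squared coordinate differences after optimal
#'   rotation of `b` onto `a`
#' @export
procrustes_distance <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); a <- a / sqrt(sum(a^2))
  b <- sweep(b, 2, colMeans(b)); b <- b / sqrt(sum(b^2))
  b <- b %*% .opa_rotate(b, a)
  sqrt(sum((a - b)^2))
}

#' Principal components of Procrustes shape coordinates
#'
#' Flattens the aligned configurations, projects them into the tangent
#' space at the mean shape (component along the mean removed), and runs an
#' ordinary PCA. Loading signs are fixed so each loading vector's
#' largest-magnitude element is positive, making score signs reproducible.
#'
#' @param gpa_fit result of [gpa()]
#' @param n_pc number of components to keep (default all with positive
#'   variance)
#' @return list: `scores` (N x n_pc), `loadings`, `variance_fraction`
#' @export
shape_pca <- function(gpa_fit, n_pc = NULL) {
  A <- unclass(gpa_fit$aligned)
  N <- dim(A)[1]
  if (N <= 2) stop_config("shape PCA needs more than 2 configurations")
  X <- t(vapply(seq_len(N), function(i) as.numeric(A[i, , ]),
                numeric(prod(dim(A)[2:3]))))
  m <- as.numeric(gpa_fit$mean_shape)
  m <- m / sqrt(sum(m^2))
  X <- X - X %*% m %*% t(m)          # tangent-space projection
  X <- sweep(X, 2, colMeans(X))
  pc <- stats::prcomp(X, center = FALSE)
  keep <- pc$sdev^2 > 1e-12 * pc$sdev[1]^2
  if (!is.null(n_pc)) keep <- keep & seq_along(keep) <= n_pc
  L <- pc$rotation[, keep, drop = FALSE]
  flip <- apply(L, 2, function(v) sign(v[which.max(abs(v))]))
  L <- sweep(L, 2, flip, `*`)
  scores <- X %*% L
  vf <- pc$sdev[keep]^2 / sum(pc$sdev^2)
  rownames(scores) <- dimnames(A)[[1]]
  list(scores = scores, loadings = L, variance_fraction = vf)
}

#' All pairwise inter-landmark distances
#'
#' @param landmarks a [landmark_set()] (raw, unscaled coordinates)
#' @return N x L(L-1)/2 matrix; columns named `lmA.lmB`
#' @export
interlandmark_distances <- function(landmarks) {
  A <- unclass(landmarks)
  L <- dim(A)[2]
  pairs <- utils::combn(L, 2)
  out <- apply(A, 1, function(m) {
    sqrt(rowSums((m[pairs[1, ], , drop = FALSE] - m[pairs[2, ], , drop = FALSE])^2))
  })
  out <- t(out)
  colnames(out) <- paste(dimnames(A)[[2]][pairs[1, ]],
                         dimnames(A)[[2]][pairs[2, ]], sep = ".")
  rownames(out) <- dimnames(A)[[1]]
  out
}

#' Regression scan of all inter-landmark distances on ancestry
#'
#' Computes the L(L-1)/2 Euclidean distances per individual from raw
#' coordinates and regresses each on ancestry plus covariates in a single
#' multi-response least-squares fit, flagging effects at the Bonferroni
#' threshold over all distances (for L = 36 the family has 630 tests, so a
#' family alpha of ~6e-4 puts the per-test threshold at 1e-6).
#'
#' @param landmarks a [landmark_set()]
#' @param design an [ancestry_design()] (rows matching configurations)
#' @param alpha_family family-wise alpha (default 0.00063, i.e. per-test
#'   1e-6 at 630 distances)
#' @param extra_covariates as in [fit_phenotype_model()]
#' @return data.frame: distance, coef/p for qEUR and qAFR, per-test
#'   threshold, significance flags
#' @export
interlandmark_scan <- function(landmarks, design, alpha_family = 0.00063,
                               extra_covariates = NULL) {
  Dm <- interlandmark_distances(landmarks)
  fml <- .design_formula("..dummy", design, TRUE, extra_covariates)
  rhs_vars <- setdiff(all.vars(fml), "..dummy")
  cc <- stats::complete.cases(design$data[, rhs_vars])
  dat <- design$data[cc, rhs_vars, drop = FALSE]
  X <- stats::model.matrix(stats::reformulate(attr(stats::terms(fml),
                                                   "term.labels")), data = dat)
  Y <- Dm[cc, , drop = FALSE]
  fit <- stats::lm.fit(X, Y)
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  sigma2 <- colSums(fit$residuals^2) / (n - p)
  thr <- alpha_family / ncol(Y)
  get <- function(term) {
    j <- match(term, colnames(X))
    b <- fit$coefficients[j, ]
    se <- sqrt(XtXinv[j, j] * sigma2)
    p_ <- 2 * stats::pt(-abs(b / se), df = n - p)
    list(b = b, p = p_)
  }
  e <- get("qEUR"); a <- get("qAFR")
  data.frame(distance = colnames(Y),
             coef_EUR = e$b, p_EUR = e$p, coef_AFR = a$b, p_AFR = a$p,
             threshold = thr, sig_EUR = e$p < thr, sig_AFR = a$p < thr,
             row.names = NULL)
}

#' Read / write landmarks as long-format CSV
#'
#' Columns: sample_id, landmark_id, x, y, z.
#'
#' @param landmarks a [landmark_set()]
#' @param path file path
#' @export
write_landmarks_csv <- function(landmarks, path) {
  A <- unclass(landmarks)
  df <- expand.grid(landmark_id = dimnames(A)[[2]],
                    sample_id = dimnames(A)[[1]],
                    stringsAsFactors = FALSE)[, 2:1]
  df$x <- as.numeric(t(A[, , 1]))
  df$y <- as.numeric(t(A[, , 2]))
  df$z <- as.numeric(t(A[, , 3]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sids <- unique(df$sample_id); lids <- unique(df$landmark_id)
  A <- array(NA_real_, c(length(sids), length(lids), 3),
             dimnames = list(sids, lids, c("x", "y", "z")))
  i <- match(df$sample_id, sids); j <- match(df$landmark_id, lids)
  A[cbind(i, j, 1)] <- df$x
  A[cbind(i, j, 2)] <- df$y
  A[cbind(i, j, 3)] <- df$z
  landmark_set(A)
}
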