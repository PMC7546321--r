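#' Voxel-wise two-sample GLM with covariates of no interest
#'
#' Fits, at every voxel, `gfc ~ intercept + group + covariates` by ordinary
#' least squares and reports the t statistic of the group coefficient.
#' Groups are coded patient = 1, control = 0, so negative t means lower GFC
#' in patients. The default covariates downstream are mean framewise
#' displacement and age.
#'
#' @param gfc_stack Subjects x voxels matrix of GFC values (one row per
#'   subject, columns in mask order).
#' @param group Factor/character/0-1 vector; patients are the 1 level.
#' @param covariates Optional data.frame or matrix of numeric covariates
#'   (e.g. `data.frame(mean_fd, age)`).
#' @return Object of class `group_stat_map`: `t` (per voxel), `df`,
#'   `beta_group`, `se_group`, `zero_variance` flags, `design`.
#' @export
fit_voxelwise_glm <- function(gfc_stack, group, covariates = NULL) {
  g <- code_group(group)
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(colnames(cv)))
      colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  if (nrow(X) != nrow(gfc_stack))
    stop("design has ", nrow(X), " rows but stack has ", nrow(gfc_stack),
         " subjects")
  qr_ <- qr(X)
  if (qr_$rank < ncol(X))
    stop("collinear design; offending column(s): ",
         paste(colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]], collapse = ", "))
  fit <- glm_group_t(gfc_stack, X)
  structure(list(t = fit$t, df = fit$df, beta_group = fit$beta,
                 se_group = fit$se, zero_variance = fit$zero_variance,
                 design = X),
            class = "group_stat_map")
}

code_group <- function(group) {
  if (is.numeric(group)) {
    if (!all(group %in% c(0, 1))) stop("numeric group must be 0/1")
    return(as.numeric(group))
  }
  g <- as.character(group)
  lv <- sort(unique(g))
  if (!all(lv %in% c("patient", "control")) || length(lv) != 2)
    stop("group must be patient/control (or 0/1) with both levels present")
  as.numeric(g == "patient")
}

# Vectorised per-voxel group t for a fixed design. The group coefficient is
# column 2 of X.
glm_group_t <- function(Y, X) {
  XtXi <- solve(crossprod(X))
  A <- XtXi %*% t(X)                      # p x N
  beta <- A %*% Y                         # p x V
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- unname(colSums(res^2)) / df
  zero <- sigma2 < .Machine$double.eps
  se <- sqrt(pmax(sigma2, .Machine$double.eps) * XtXi[2, 2])
  t <- unname(beta[2, ]) / se
  t[zero] <- 0                             # 0/0 guard: no variance, no effect
  list(t = t, df = df, beta = unname(beta[2, ]), se = se,
       zero_variance = zero)
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat(sprintf("<group_stat_map> %d voxels, df = %d, t range [%.3f, %.3f]",
              length(x$t), x$df, min(x$t), max(x$t)))
  if (!is.null(x$p_fwe))
    cat(sprintf(", %d voxel(s) FWE-significant at alpha = %g",
                sum(x$significant), x$alpha))
  cat("\n")
  invisible(x)
}

#' Permutation max-|t| family-wise error control (Freedman-Lane)
#'
#' Controls the probability of any false-positive voxel by the permutation
#' distribution of the maximum absolute group t over the mask. Nuisance
#' covariates are handled by the Freedman-Lane scheme: the maps are
#' regressed on the covariates alone, the residuals are permuted across
#' subjects, the covariate fit is added back, and the full model is refit —
#' so the null distribution respects the covariate structure. The adjusted
#' p-value of voxel v is `(1 + #{max_perm >= |t_obs(v)|}) / (n_perm + 1)`.
#'
#' @inheritParams fit_voxelwise_glm
#' @param n_perm Number of permutations (default 1000, minimum 100).
#' @param alpha Family-wise significance level (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return A `group_stat_map` with `p_fwe`, `significant`, `max_null` (the
#'   permutation maxima), `alpha`, `n_perm` added.
#' @export
permutation_fwe <- function(gfc_stack, group, covariates = NULL,
                            n_perm = 1000L, alpha = 0.05, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (n_perm < 1 / alpha - 1)
    warning("n_perm = ", n_perm, " cannot resolve p-values below alpha = ",
            alpha)
  obs <- fit_voxelwise_glm(gfc_stack, group, covariates)
  X <- obs$design
  N <- nrow(X)
  Z <- X[, -2, drop = FALSE]               # nuisance-only design
  qz <- qr(Z)
  fitted_z <- qr.fitted(qz, gfc_stack)
  resid_z <- gfc_stack - fitted_z

  max_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- sample.int(N)
      Yp <- fitted_z + resid_z[perm, , drop = FALSE]
      max(abs(glm_group_t(Yp, X)$t))
    }, numeric(1))
  })

  abs_t <- abs(obs$t)
  # +1 for the identity permutation in both numerator and denominator
  p_fwe <- (1 + vapply(abs_t, function(ti) sum(max_null >= ti),
                       numeric(1))) / (n_perm + 1)
  obs$p_fwe <- p_fwe
  obs$significant <- p_fwe < alpha
  obs$max_null <- max_null
  obs$alpha <- alpha
  obs$n_perm <- n_perm
  obs$seed <- seed
  obs
}

neighbor_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & rowSums(off != 0) <= 2,
                 "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Extract connected suprathreshold clusters
#'
#' Connected components of the significant-voxel mask under 6-, 18- or
#' 26-connectivity (default 26, the face-edge-corner convention of the
#' common neuroimaging toolboxes). Each cluster reports its size, peak
#' (voxel of maximum |t|), peak mm coordinate via the affine, peak t and
#' effect direction. Clusters are sorted by size (descending), ties broken
#' by peak |t| then lexicographic peak index.
#'
#' @param significant Logical vector in mask-column order (or logical 3D
#'   array on the mask grid).
#' @param t_values Numeric vector of t statistics in mask-column order.
#' @param mask The `gm_mask` the vectors live on.
#' @param connectivity 6, 18 or 26.
#' @return List of `cluster_result` objects (empty list if nothing is
#'   significant). Each has `columns` (indices into the mask column order),
#'   `size`, `peak_voxel` (1-based i,j,k), `peak_mm`, `peak_t`, `direction`.
#' @export
extract_clusters <- function(significant, t_values, mask, connectivity = 26) {
  off <- neighbor_offsets(connectivity)
  d <- dim(mask$data)
  sig_arr <- array(FALSE, d)
  cols_lin <- which(mask$data)             # mask column order -> linear index
  if (is.array(significant)) {
    sig_arr <- significant
  } else {
    sig_arr[cols_lin[significant]] <- TRUE
  }
  col_of <- array(0L, d)
  col_of[cols_lin] <- seq_along(cols_lin)

  lin_sig <- which(sig_arr)
  if (length(lin_sig) == 0L) return(list())
  labels <- array(0L, d)

  clusters <- list()
  cur <- 0L
  for (s in seq_along(lin_sig)) {
    start <- lin_sig[s]
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    members <- integer(0)
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, v)
      vi <- drop(arrayInd(v, d))
      nb <- sweep(off, 2, vi, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin_nb <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      new <- lin_nb[sig_arr[lin_nb] & labels[lin_nb] == 0L]
      labels[new] <- cur
      queue <- c(queue, new)
    }
    cols <- sort(col_of[members])
    cols <- cols[cols > 0]
    tv <- t_values[cols]
    peak_i <- cols[order(-abs(tv), cols)][1]
    peak_lin <- cols_lin[peak_i]
    pk <- arrayInd(peak_lin, d)
    clusters[[cur]] <- structure(
      list(columns = cols, size = length(cols),
           peak_voxel = drop(pk),
           peak_mm = drop(voxel_to_mm(pk, mask$affine)),
           peak_t = t_values[peak_i],
           direction = if (t_values[peak_i] < 0) "decreased" else "increased"),
      class = "cluster_result")
  }
  ord <- order(-vapply(clusters, `[[`, numeric(1), "size"),
               -abs(vapply(clusters, `[[`, numeric(1), "peak_t")),
               vapply(clusters, function(cl) cl$columns[1], numeric(1)))
  clusters[ord]
}

#' Tabulate clusters in report form
#'
#' @param clusters List returned by [extract_clusters].
#' @return data.frame with columns cluster_id, size_voxels, peak_x_mm,
#'   peak_y_mm, peak_z_mm, peak_t, direction (zero rows if no clusters).
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0L)
    return(data.frame(cluster_id = integer(0), size_voxels = integer(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0), peak_t = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  data.frame(
    cluster_id = seq_along(clusters),
    size_voxels = vapply(clusters, `[[`, numeric(1), "size"),
    peak_x_mm = vapply(clusters, function(cl) cl$peak_mm[1], numeric(1)),
    peak_y_mm = vapply(clusters, function(cl) cl$peak_mm[2], numeric(1)),
    peak_z_mm = vapply(clusters, function(cl) cl$peak_mm[3], numeric(1)),
    peak_t = vapply(clusters, `[[`, numeric(1), "peak_t"),
    direction = vapply(clusters, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE)
}
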