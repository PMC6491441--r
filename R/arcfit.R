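#' Fit a circular arc to a cell centerline
#'
#' The core shape model: the cell centerline is fitted with a circular
#' arc ("oval" fit) whose arc angle gives the cell length, `L = R *
#' |dphi|`, and whose circle defines the inner (concave, toward the arc
#' center) and outer (convex) sides of a curved cell. A circle rather
#' than a general ellipse is used deliberately: centerlines subtend
#' short arcs on which ellipse fitting is ill-conditioned, while a
#' circle has a closed-form arc length and an unambiguous inner/outer
#' side.
#'
#' The circle is estimated by the algebraic least-squares fit of Pratt
#' (eigenvector of the inverse-constraint moment matrix), which is
#' unbiased for small arcs. Pole angles come from projecting the first
#' and last centerline points onto the circle; the signed sweep is the
#' short way round (< pi). If the fitted radius exceeds
#' `straightness_ratio` times the pole chord — or the algebraic fit
#' degenerates — the cell is treated as straight: a total-least-squares
#' line fit with poles at the endpoint projections.
#'
#' @param centerline Matrix or data frame of ordered centerline points
#'   (columns x, y in nm; >= 5 points).
#' @param straightness_ratio Radius/chord ratio beyond which the cell is
#'   called straight (default 15).
#' @return Object of class `arc_model`: list with `kind` ("arc" or
#'   "straight"), `center_nm`, `radius_nm`, `phi_a`, `phi_b`, `sweep`
#'   (signed, a to b), `pole_a_nm`, `pole_b_nm`, `length_nm`, `rmse_nm`,
#'   `n`. For straight fits `axis` holds the unit direction a to b.
#' @seealso [project_to_cell_frame()], [tidy.arc_model()]
#' @export
fit_arc <- function(centerline, straightness_ratio = 15) {
  pts <- as.matrix(centerline)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 5L) abort("fit_arc: need at least 5 centerline points")

  ctr <- colMeans(pts)
  xc <- pts[, 1] - ctr[1]; yc <- pts[, 2] - ctr[2]
  chord <- sqrt(sum((pts[n, ] - pts[1, ])^2))
  if (chord <= 0) abort("fit_arc: coincident endpoints")

  fit <- pratt_circle(xc, yc)
  straight <- is.null(fit) || !is.finite(fit$r) ||
    fit$r > straightness_ratio * chord

  if (!straight) {
    cen <- c(fit$cx + ctr[1], fit$cy + ctr[2])
    R <- fit$r
    phi <- atan2(pts[, 2] - cen[2], pts[, 1] - cen[1])
    phi_a <- phi[1]; phi_b <- phi[n]
    sweep <- wrap_angle(phi_b - phi_a)
    if (sweep == 0) {
      straight <- TRUE
    } else {
      pole_a <- cen + R * c(cos(phi_a), sin(phi_a))
      pole_b <- cen + R * c(cos(phi_b), sin(phi_b))
      rad <- sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2)
      model <- structure(list(
        kind = "arc", center_nm = cen, radius_nm = R,
        phi_a = phi_a, phi_b = phi_b, sweep = sweep,
        pole_a_nm = pole_a, pole_b_nm = pole_b,
        length_nm = R * abs(sweep),
        rmse_nm = sqrt(mean((rad - R)^2)),
        n = n), class = "arc_model")
      return(model)
    }
  }

  # straight fallback: total least squares via the principal axis
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  u <- pc$rotation[, 1]
  t <- (pts - matrix(pc$center, n, 2, byrow = TRUE)) %*% u
  if (t[n] < t[1]) { u <- -u; t <- -t }   # axis runs first -> last point
  pole_a <- pc$center + as.numeric(t[1]) * u
  pole_b <- pc$center + as.numeric(t[n]) * u
  perp <- (pts - matrix(pc$center, n, 2, byrow = TRUE)) %*% c(-u[2], u[1])
  structure(list(
    kind = "straight", center_nm = c(NA_real_, NA_real_),
    radius_nm = NA_real_, phi_a = NA_real_, phi_b = NA_real_,
    sweep = NA_real_,
    pole_a_nm = as.numeric(pole_a), pole_b_nm = as.numeric(pole_b),
    axis = as.numeric(u),
    length_nm = sqrt(sum((pole_b - pole_a)^2)),
    rmse_nm = sqrt(mean(perp^2)),
    n = n), class = "arc_model")
}

# Pratt algebraic circle fit on centered coordinates; returns NULL when
# the generalized eigenproblem offers no usable circle solution
pratt_circle <- function(x, y) {
  z <- x^2 + y^2
  A <- cbind(z, x, y, 1)
  M <- crossprod(A) / length(x)
  Binv <- matrix(c(0, 0, 0, -0.5,
                   0, 1, 0, 0,
                   0, 0, 1, 0,
                   -0.5, 0, 0, 0), 4, 4, byrow = TRUE)
  ev <- tryCatch(eigen(Binv %*% M), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  vals <- ev$values
  ok <- abs(Im(vals)) < 1e-8 & Re(vals) > -1e-8
  if (!any(ok)) return(NULL)
  idx <- which(ok)[which.min(Re(vals)[ok])]
  v <- Re(ev$vectors[, idx])
  a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
  if (abs(a) < 1e-14) return(NULL)
  cx <- -b / (2 * a); cy <- -cc / (2 * a)
  disc <- b^2 + cc^2 - 4 * a * d
  if (disc <= 0) return(NULL)
  list(cx = cx, cy = cy, r = sqrt(disc) / (2 * abs(a)))
}

#' @export
print.arc_model <- function(x, ...) {
  if (x$kind == "arc") {
    cat("<arc_model> circular arc: R = ", signif(x$radius_nm, 6),
        " nm, sweep = ", signif(x$sweep * 180 / pi, 4),
        " deg, length = ", signif(x$length_nm, 6),
        " nm, rmse = ", signif(x$rmse_nm, 3), " nm\n", sep = "")
  } else {
    cat("<arc_model> straight segment: length = ", signif(x$length_nm, 6),
        " nm, rmse = ", signif(x$rmse_nm, 3), " nm\n", sep = "")
  }
  invisible(x)
}

#' Tidy an arc model
#'
#' broom-style `tidy()`: one row per fitted parameter.
#'
#' @param x An `arc_model`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.arc_model <- function(x, ...) {
  if (x$kind == "arc") {
    tibble(term = c("center_x_nm", "center_y_nm", "radius_nm",
                    "phi_a_rad", "phi_b_rad", "sweep_rad", "length_nm"),
           estimate = c(x$center_nm, x$radius_nm, x$phi_a, x$phi_b,
                        x$sweep, x$length_nm))
  } else {
    tibble(term = c("pole_a_x_nm", "pole_a_y_nm", "pole_b_x_nm",
                    "pole_b_y_nm", "length_nm"),
           estimate = c(x$pole_a_nm, x$pole_b_nm, x$length_nm))
  }
}

#' Glance at an arc model
#'
#' broom-style `glance()`: one-row fit summary.
#'
#' @param x An `arc_model`.
#' @param ... Unused.
#' @return One-row tibble: `kind`, `length_nm`, `radius_nm`, `rmse_nm`, `n`.
#' @export
glance.arc_model <- function(x, ...) {
  tibble(kind = x$kind, length_nm = x$length_nm,
         radius_nm = x$radius_nm, rmse_nm = x$rmse_nm, n = x$n)
}

# Fit the arc of a meshed cell: the circle is estimated on the
# cap-trimmed interior centerline (cap-region midpoints pair across
# unequal bank lengths and sit a nanometre or two inside the true
# midline, biasing the radius), then pole angles and length are
# re-anchored at the full centerline endpoints (the pole tips).
fit_cell_arc <- function(mesh, straightness_ratio = 15) {
  cl <- mesh_centerline(mesh)
  n <- nrow(cl)
  w_half <- stats::median(sqrt((mesh$x_left - mesh$x_right)^2 +
                               (mesh$y_left - mesh$y_right)^2)[
    seq(ceiling(n / 3), floor(2 * n / 3))]) / 2
  arclen <- c(0, cumsum(sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)))
  interior <- arclen > 1.5 * w_half & arclen < max(arclen) - 1.5 * w_half
  base <- if (sum(interior) >= 5L) cl[interior, , drop = FALSE] else cl
  model <- fit_arc(base, straightness_ratio)
  rebase_arc(model, cl)
}

# recompute pole angles, poles, length and rmse of a model against a
# full centerline whose endpoints are the pole tips
rebase_arc <- function(model, cl) {
  n <- nrow(cl)
  if (model$kind == "arc") {
    cen <- model$center_nm; R <- model$radius_nm
    phi <- atan2(cl[, 2] - cen[2], cl[, 1] - cen[1])
    sweep <- wrap_angle(phi[n] - phi[1])
    if (sweep == 0) return(fit_arc(cl))
    model$phi_a <- phi[1]; model$phi_b <- phi[n]; model$sweep <- sweep
    model$pole_a_nm <- cen + R * c(cos(phi[1]), sin(phi[1]))
    model$pole_b_nm <- cen + R * c(cos(phi[n]), sin(phi[n]))
    model$length_nm <- R * abs(sweep)
    rad <- sqrt((cl[, 1] - cen[1])^2 + (cl[, 2] - cen[2])^2)
    model$rmse_nm <- sqrt(mean((rad - R)^2))
    model$n <- n
    model
  } else {
    u <- model$axis
    t <- (cl %*% u)
    a0 <- model$pole_a_nm
    ta <- ((cl[1, ] - a0) %*% u)[1]; tb <- ((cl[n, ] - a0) %*% u)[1]
    model$pole_a_nm <- a0 + ta * u
    model$pole_b_nm <- a0 + tb * u
    model$length_nm <- abs(tb - ta)
    perp <- (cl[, 1] - a0[1]) * (-u[2]) + (cl[, 2] - a0[2]) * u[1]
    model$rmse_nm <- sqrt(mean((perp - mean(perp))^2))
    model$n <- n
    model
  }
}

#' broom-style generics
#'
#' Minimal `tidy()`/`glance()` generics so fitted objects follow broom
#' conventions without requiring broom itself.
#'
#' @param x Object to summarise.
#' @param ... Method-specific arguments.
#' @name arcell-broom
NULL

#' @rdname arcell-broom
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname arcell-broom
#' @export
glance <- function(x, ...) UseMethod("glance")
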