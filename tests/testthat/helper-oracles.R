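# Independent brute-force oracles used across the suite.

# Maximum-weight one-to-one assignment by exhaustive permutation enumeration
# (rows <= cols; pads implicitly by allowing unassigned rows via subsets).
brute_max_assignment_weight <- function(wm) {
  nr <- nrow(wm); nc <- ncol(wm)
  if (nr == 0 || nc == 0) return(0)
  if (nr > nc) return(brute_max_assignment_weight(t(wm)))
  cols <- seq_len(nc)
  best <- 0
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  combs <- utils::combn(cols, nr, simplify = FALSE)
  for (cb in combs) {
    for (p in perms(cb)) {
      w <- sum(wm[cbind(seq_len(nr), p)])
      if (w > best) best <- w
    }
  }
  best
}

# Pixel-set IoU of two integer boxes under the half-open convention.
pixel_iou <- function(b1, b2) {
  px1 <- outer(b1[1]:(b1[1] + b1[3] - 1), b1[2]:(b1[2] + b1[4] - 1),
               function(x, y) paste(x, y))
  px2 <- outer(b2[1]:(b2[1] + b2[3] - 1), b2[2]:(b2[2] + b2[4] - 1),
               function(x, y) paste(x, y))
  length(intersect(px1, px2)) / length(union(px1, px2))
}

# Direct per-bin density count from worm coordinates (nested-cylinder set
# differences per territory), written independently of density_feature().
density_oracle <- function(x_ap, y_vd, z, q, dl, dz) {
  rho <- sqrt(x_ap^2 + y_vd^2)
  phi <- atan2(x_ap, y_vd)
  phi <- ifelse(phi < -pi / 2, phi + 2 * pi, phi)
  ventral <- phi <= pi / 2
  out <- numeric(4 * q)
  in_cyl <- function(t, terr) {
    zz <- switch(terr,
                 zpV = z >= 0 & ventral, zmV = z < 0 & ventral,
                 zpD = z >= 0 & !ventral, zmD = z < 0 & !ventral)
    rho <= t * dl & abs(z) <= t * dz / 2 & zz
  }
  terrs <- c("zpV", "zmV", "zpD", "zmD")
  for (t in seq_len(q)) for (k in 1:4) {
    inner <- if (t == 1) 0 else sum(in_cyl(t - 1, terrs[k]))
    out[(t - 1) * 4 + k] <- sum(in_cyl(t, terrs[k])) - inner
  }
  out
}

# Plain normalised, s-scaled softmax cross-entropy (the margin-free
# reference for the loss reduction check).
softmax_ce_oracle <- function(cvec, xi, W, s) {
  cn <- cvec / sqrt(sum(cvec^2))
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  logits <- s * as.numeric(cn %*% wn)
  -(logits[xi] - log(sum(exp(logits))))
}

# A hand-built identity worm frame: pixel coords are worm coords.
identity_frame <- function() {
  structure(list(O = c(0, 0), P_a = c(10, 0), P_p = c(-10, 0),
                 P_v = c(0, 10), P_d = c(0, -10),
                 ap = c(1, 0), vd = c(0, 1),
                 M00 = 1, M10 = 0, M01 = 0), class = "worm_frame")
}

# Filled ellipse head image at rotation theta with an anterior-biased
# intensity asymmetry: a large bright anterior spot (nerve-ring analogue) and
# a smaller posterior spot, so the anterior side holds more bright pixels.
# spots = FALSE gives a uniform ellipse.
ellipse_head_image <- function(theta_deg, W = 200, H = 200, a = 70, b = 35,
                               base = 100, spots = TRUE) {
  th <- theta_deg * pi / 180
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), times = W), H, W)
  u <- cos(th) * (X - cx) + sin(th) * (Y - cy)
  v <- -sin(th) * (X - cx) + cos(th) * (Y - cy)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  img <- matrix(0, H, W)
  img[inside] <- base
  if (spots) {
    spot <- function(uc, vc, amp, sig)
      amp * exp(-((u - uc)^2 + (v - vc)^2) / (2 * sig^2))
    # bright anterior (slightly ventral) spot + smaller posterior spot
    img[inside] <- img[inside] + spot(0.45 * a, 0.2 * b, 120, 9)[inside] +
      spot(-0.45 * a, 0, 90, 5)[inside]
  }
  img
}
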