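# Metric-learning recognition: a feed-forward embedding network maps each
# neuron's feature vector onto a scaled hypersphere; classes are columns of a
# weight matrix on the same sphere; training uses a combined angular-margin
# softmax loss and inference assigns digital IDs per volume by Hungarian
# matching on cosine distances.

normalize_rows <- function(M) {
  nr <- sqrt(rowSums(M^2))
  list(M = M / pmax(nr, 1e-12), norms = pmax(nr, 1e-12))
}
normalize_cols <- function(M) {
  nc <- sqrt(colSums(M^2))
  list(M = sweep(M, 2, pmax(nc, 1e-12), "/"), norms = pmax(nc, 1e-12))
}

# Margin-penalised logits: target class uses s*(cos(m1*theta + m2) - m3),
# all other classes s*cos(theta).
margin_logits <- function(cosm, labels, s, m1, m2, m3) {
  eps <- 1e-7
  cosm <- clamp(cosm, -1 + eps, 1 - eps)
  Z <- s * cosm
  idx <- cbind(seq_len(nrow(cosm)), labels)
  theta <- acos(cosm[idx])
  Z[idx] <- s * (cos(m1 * theta + m2) - m3)
  list(Z = Z, theta = theta, cosm = cosm, idx = idx)
}

#' Combined angular-margin softmax loss
#'
#' The embedding `c` and every class weight column are unit-normalised; with
#' `theta_j` the angle between the embedding and class j's weight vector, the
#' target-class logit is `s * (cos(m1 * theta + m2) - m3)` while other
#' classes keep `s * cos(theta_j)`; the loss is the softmax cross-entropy of
#' the target logit. With `m1 = 1, m2 = m3 = 0` this reduces exactly to
#' normalised, s-scaled softmax cross-entropy. `m1` is a multiplicative
#' angular penalty, `m2` an additive angular penalty, `m3` an additive cosine
#' penalty; all three enlarge the angular margin between identity clusters.
#'
#' @param c numeric matrix of embeddings (rows) or a single vector.
#' @param xi integer class label(s) in `1..ncol(W)`.
#' @param W weight matrix, one column per class.
#' @param s hypersphere radius (scale), > 0.
#' @param m1,m2,m3 margin penalties.
#' @return Mean loss (scalar).
#' @export
margin_loss <- function(c, xi, W, s = 30, m1 = 1.05, m2 = 0, m3 = 0.05) {
  stopif_not(s > 0, "s must be > 0")
  if (is.null(dim(c))) c <- matrix(c, nrow = 1)
  stopif_not(all(xi >= 1 & xi <= ncol(W)), "label out of range")
  Cn <- normalize_rows(c)$M
  Wn <- normalize_cols(W)$M
  ml <- margin_logits(Cn %*% Wn, xi, s, m1, m2, m3)
  Zs <- ml$Z - apply(ml$Z, 1, max)
  logp <- Zs - log(rowSums(exp(Zs)))
  -mean(logp[ml$idx])
}

recognizer_forward <- function(p, X) {
  S1 <- addb(X %*% p$W1, p$b1); H1 <- relu(S1)
  S2 <- addb(H1 %*% p$W2, p$b2); H2 <- relu(S2)
  C <- addb(H2 %*% p$W3, p$b3)
  list(S1 = S1, H1 = H1, S2 = S2, H2 = H2, C = C)
}

# Loss + gradients for one (full) batch under the margin softmax.
recognizer_backward <- function(p, X, fw, labels, s, m1, m2, m3) {
  n <- nrow(X)
  nc <- normalize_rows(fw$C); Cn <- nc$M
  nw <- normalize_cols(p$Wcls); Wn <- nw$M
  ml <- margin_logits(Cn %*% Wn, labels, s, m1, m2, m3)
  Zs <- ml$Z - apply(ml$Z, 1, max)
  P <- exp(Zs) / rowSums(exp(Zs))
  loss <- -mean(log(pmax(P[ml$idx], 1e-12)))
  Y <- matrix(0, n, ncol(Wn)); Y[ml$idx] <- 1
  dZ <- (P - Y) / n
  # d logit / d cos(theta): s off-target; smooth composite through acos on
  # the target (clipped away from the endpoints)
  sin_t <- sqrt(pmax(1 - ml$cosm[ml$idx]^2, 1e-7))
  Gcos <- dZ * s
  Gcos[ml$idx] <- dZ[ml$idx] * s * m1 * sin(m1 * ml$theta + m2) / sin_t
  dCn <- Gcos %*% t(Wn)
  dWn <- t(Cn) %*% Gcos
  # through row/column normalisation
  dC <- (dCn - rowSums(dCn * Cn) * Cn) / nc$norms
  dW <- sweep(dWn - sweep(Wn, 2, colSums(dWn * Wn), "*"), 2, nw$norms, "/")
  dS2 <- (dC %*% t(p$W3)) * (fw$S2 > 0)
  dS1 <- (dS2 %*% t(p$W2)) * (fw$S1 > 0)
  grads <- list(W1 = t(X) %*% dS1, b1 = colSums(dS1),
                W2 = t(fw$H1) %*% dS2, b2 = colSums(dS2),
                W3 = t(fw$H2) %*% dC, b3 = colSums(dC),
                Wcls = dW)
  list(loss = loss, grads = grads)
}

adam_step <- function(params, state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the digital-ID recognition model
#'
#' Embeds each neuron's concatenated density + KNN feature vector on a
#' d-dimensional hypersphere of radius `s` and minimises the combined
#' angular-margin softmax loss ([margin_loss()]) over the labelled training
#' neurons with Adam. One class per digital ID present in the labels, plus
#' one extra class reserved for neurons outside the tracked ID set (it is
#' excluded from matching at inference). Reproducible given `seed`.
#'
#' @param features feature tibble (rows from all training volumes; see
#'   [featurize_volume()]) with a `label` column of digital IDs, or pass
#'   `labels` separately. Rows with `NA` label are assigned to the extra
#'   class.
#' @param labels optional vector of digital IDs (overrides the column).
#' @param hidden widths of the two hidden layers.
#' @param d embedding dimension.
#' @param s hypersphere radius.
#' @param m1,m2,m3 margin penalties (defaults 1.05, 0, 0.05).
#' @param epochs,lr Adam settings (full-batch).
#' @param val_features,val_labels optional held-out set; top-1 accuracy is
#'   recorded per epoch.
#' @param seed integer seed.
#' @return An object of class `wt_recognizer`.
#' @export
train_recognizer <- function(features, labels = NULL, hidden = c(256L, 128L),
                             d = 128L, s = 30, m1 = 1.05, m2 = 0, m3 = 0.05,
                             epochs = 200L, lr = 2e-3,
                             val_features = NULL, val_labels = NULL,
                             seed = 0L) {
  X <- feature_matrix(features)
  labels <- labels %||% features$label
  stopif_not(length(labels) == nrow(X), "one label per feature row required")
  class_ids <- sort(unique(labels[!is.na(labels)]))
  stopif_not(length(class_ids) >= 2, "need at least 2 classes")
  N <- length(class_ids) + 1L                     # +1 extra class
  y <- match(labels, class_ids)
  y[is.na(y)] <- N
  if (!any(y == N))
    NULL  # extra class simply keeps its random column
  mu <- colMeans(X); sdv <- pmax(apply(X, 2, sd), 1e-6)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  with_seed(child_seed(seed, 0L, 13L), {
    p <- list(W1 = init_mat(ncol(Xs), hidden[1]), b1 = rep(0, hidden[1]),
              W2 = init_mat(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
              W3 = init_mat(hidden[2], d), b3 = rep(0, d),
              Wcls = init_mat(d, N))
    state <- list(t = 0, m = lapply(p, function(q) q * 0),
                  v = lapply(p, function(q) q * 0))
    history <- tibble(epoch = integer(), loss = numeric(), val_top1 = numeric())
    Xv <- NULL
    if (!is.null(val_features)) {
      Xv <- feature_matrix(val_features)
      Xv <- sweep(sweep(Xv, 2, mu), 2, sdv, "/")
      val_labels <- val_labels %||% val_features$label
    }
    for (ep in seq_len(epochs)) {
      fw <- recognizer_forward(p, Xs)
      bw <- recognizer_backward(p, Xs, fw, y, s, m1, m2, m3)
      upd <- adam_step(p, state, bw$grads, lr)
      p <- upd$params; state <- upd$state
      val_top1 <- NA_real_
      if (!is.null(Xv) && (ep %% 10 == 0 || ep == epochs)) {
        Cn <- normalize_rows(recognizer_forward(p, Xv)$C)$M
        Wn <- normalize_cols(p$Wcls)$M
        pred <- class_ids[pmin(apply(Cn %*% Wn[, -N, drop = FALSE], 1,
                                     which.max), length(class_ids))]
        val_top1 <- mean(pred == val_labels)
      }
      history <- bind_rows(history,
                           tibble(epoch = ep, loss = bw$loss,
                                  val_top1 = val_top1))
    }
    structure(list(params = p, mu = mu, sd = sdv, class_ids = class_ids,
                   N = N, d = d, s = s, m1 = m1, m2 = m2, m3 = m3,
                   history = history, n_train = nrow(Xs), seed = seed),
              class = "wt_recognizer")
  })
}

#' Embed neuron features with a trained recognizer
#'
#' @param model a `wt_recognizer`.
#' @param features feature tibble or matrix.
#' @return Unit-normalised embedding matrix (one row per neuron).
#' @export
embed_features <- function(model, features) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  normalize_rows(recognizer_forward(model$params, Xs)$C)$M
}

# Minimise the trace of a cosine-distance matrix by the Hungarian method;
# rectangular matrices are padded with `pad_cost` and padded assignments are
# reported as unassigned (NA).
assign_by_distance <- function(D, col_ids, pad_cost = 2) {
  nr <- nrow(D); nc <- ncol(D)
  n <- max(nr, nc)
  sq <- matrix(pad_cost, n, n)
  sq[seq_len(nr), seq_len(nc)] <- D
  sq <- pmax(sq, 0)   # guard tiny negative cosine-distance roundoff
  sol <- as.integer(clue::solve_LSAP(sq))
  cols <- sol[seq_len(nr)]
  assigned <- ifelse(cols <= nc, col_ids[pmin(cols, nc)], NA)
  dist <- ifelse(cols <= nc, D[cbind(seq_len(nr), pmin(cols, nc))], NA_real_)
  tibble(row = seq_len(nr), assigned_id = assigned, distance = dist)
}

#' Assign digital IDs within an animal
#'
#' Computes the cosine-distance matrix `D[i, j] = 1 - cos(c_i, w_j)` between
#' the volume's embedded neurons and the trained class weight columns
#' (excluding the extra class) and finds the permutation minimising its trace
#' with the Hungarian method. When neurons and classes differ in number, the
#' matrix is padded at distance 2 (the cosine-distance maximum) and the
#' extras are left unassigned.
#'
#' @param model a `wt_recognizer`.
#' @param features feature tibble of one volume.
#' @return A tibble `object_id, assigned_id, distance` (class `wt_assignment`)
#'   with the full distance matrix in attribute `"D"`.
#' @export
assign_ids_within <- function(model, features) {
  Cn <- embed_features(model, features)
  Wn <- normalize_cols(model$params$Wcls)$M[, -model$N, drop = FALSE]
  D <- 1 - Cn %*% Wn
  res <- assign_by_distance(D, model$class_ids)
  out <- tibble(object_id = features$object_id,
                assigned_id = res$assigned_id, distance = res$distance)
  attr(out, "D") <- D
  class(out) <- c("wt_assignment", class(out))
  out
}

#' Assign digital IDs across animals via a template volume
#'
#' Replaces the class weight matrix by the embeddings of a template volume's
#' neurons (each template neuron becomes one class column), then matches the
#' test volume's embeddings to them as in [assign_ids_within()].
#'
#' @param model a `wt_recognizer` (supplies the embedding network).
#' @param template_features feature tibble of the template volume.
#' @param test_features feature tibble of the volume to annotate.
#' @param template_ids IDs carried by the template neurons (default their
#'   `label` column, else their `object_id`).
#' @return A `wt_assignment` tibble as in [assign_ids_within()].
#' @export
assign_ids_across <- function(model, template_features, test_features,
                              template_ids = NULL) {
  template_ids <- template_ids %||% template_features[["label"]] %||%
    template_features[["object_id"]]
  Ct <- embed_features(model, template_features)
  Cn <- embed_features(model, test_features)
  D <- 1 - Cn %*% t(Ct)
  res <- assign_by_distance(D, template_ids)
  out <- tibble(object_id = test_features$object_id,
                assigned_id = res$assigned_id, distance = res$distance)
  attr(out, "D") <- D
  class(out) <- c("wt_assignment", class(out))
  out
}

#' Top-1 tracking accuracy
#'
#' Fraction of neurons whose assigned digital ID equals the ground truth,
#' averaged per volume and then across volumes. Unassigned neurons count as
#' wrong.
#'
#' @param assignments tibble with `assigned_id`, `true_id` and (optionally)
#'   `volume` columns; without `volume` all rows form one volume.
#' @param true_ids optional vector overriding the `true_id` column.
#' @return Scalar top-1 accuracy in `[0, 1]`.
#' @export
evaluate_tracking <- function(assignments, true_ids = NULL) {
  tr <- true_ids %||% assignments[["true_id"]]
  stopif_not(length(tr) == nrow(assignments) && any(!is.na(tr)),
             "no labelled neurons to evaluate")
  vol <- assignments[["volume"]] %||% rep(1L, nrow(assignments))
  ok <- !is.na(tr)
  hit <- !is.na(assignments$assigned_id) & assignments$assigned_id == tr
  mean(tapply(hit[ok], vol[ok], mean))
}
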