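# Classification losses: cross entropy, label smoothing, and the
# temperature-softened distillation objective. Natural logarithm throughout;
# probabilities are floored at 1e-12 before log as a numerical guard.

PROB_FLOOR <- 1e-12

check_onehot <- function(y) {
  if (any(!(y %in% c(0, 1))) || sum(y) != 1)
    stop("y must be a one-hot vector")
  invisible(y)
}

check_prob <- function(p) {
  if (any(p < -1e-9) || any(p > 1 + 1e-9) || abs(sum(p) - 1) > 1e-6)
    stop("p must be a probability vector summing to 1")
  invisible(p)
}

#' Smoothing specification
#'
#' @param epsilon smoothing coefficient in `[0, 1]` (default 0.1, the
#'   conventional value).
#' @param K class count (>= 2).
#' @export
smoothing_spec <- function(epsilon = 0.1, K = 5L) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (K < 2) stop("K must be >= 2")
  structure(list(epsilon = epsilon, K = as.integer(K)), class = "smoothing_spec")
}

#' Smooth a one-hot label
#'
#' `y_i -> (1 - epsilon) * y_i + epsilon / K`. The result still sums to 1;
#' `epsilon = 0` returns the hard label and `epsilon = 1` the uniform
#' distribution.
#'
#' @param y one-hot vector of length K.
#' @param spec a [smoothing_spec()].
#' @return soft label vector.
#' @export
smooth_labels <- function(y, spec = smoothing_spec(K = length(y))) {
  check_onehot(y)
  if (length(y) != spec$K) stop("length(y) must equal spec$K")
  (1 - spec$epsilon) * y + spec$epsilon / spec$K
}

#' Label-smoothing loss
#'
#' `-sum_i ytilde_i log p_i` with the smoothed target
#' `ytilde = (1 - epsilon) y + epsilon / K`.
#'
#' @param p predicted class probabilities (length K).
#' @param y one-hot true label.
#' @param spec a [smoothing_spec()].
#' @return nonnegative scalar.
#' @export
label_smoothing_loss <- function(p, y, spec = smoothing_spec(K = length(y))) {
  if (length(p) != length(y)) stop("p and y must have equal length")
  check_prob(p)
  yt <- smooth_labels(y, spec)
  -sum(yt * log(pmax(p, PROB_FLOOR)))
}

#' Cross-entropy loss
#'
#' `-log p_true` for a one-hot target.
#'
#' @param p predicted class probabilities.
#' @param y one-hot true label.
#' @return nonnegative scalar.
#' @export
cross_entropy <- function(p, y) {
  if (length(p) != length(y)) stop("p and y must have equal length")
  check_prob(p); check_onehot(y)
  -sum(y * log(pmax(p, PROB_FLOOR)))
}

#' Distillation specification
#'
#' @param T softmax temperature (> 0, default 4).
#' @param alpha weight of the softened teacher-matching term in `[0, 1]`
#'   (default 0.7).
#' @export
distill_spec <- function(T = 4, alpha = 0.7) {
  if (T <= 0) stop("T must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  structure(list(T = T, alpha = alpha), class = "distill_spec")
}

softmax_vec <- function(z) { e <- exp(z - max(z)); e / sum(e) }

kl_div <- function(p, q) sum(p * (log(pmax(p, PROB_FLOOR)) - log(pmax(q, PROB_FLOOR))))

#' Knowledge-distillation loss
#'
#' `alpha * T^2 * KL(softmax(teacher / T) || softmax(student / T)) +
#' (1 - alpha) * cross_entropy(softmax(student), y)`. The teacher is the
#' reference distribution (forward KL) and its logits are treated as
#' constants.
#'
#' @param student_logits,teacher_logits equal-length logit vectors.
#' @param y one-hot true label.
#' @param spec a [distill_spec()].
#' @return scalar loss.
#' @export
distillation_loss <- function(student_logits, teacher_logits, y,
                              spec = distill_spec()) {
  if (length(student_logits) != length(teacher_logits))
    stop("student and teacher logits must have equal length")
  soft <- kl_div(softmax_vec(teacher_logits / spec$T),
                 softmax_vec(student_logits / spec$T))
  hard <- cross_entropy(softmax_vec(student_logits), y)
  spec$alpha * spec$T^2 * soft + (1 - spec$alpha) * hard
}

# ---- batched loss + gradient on logits (training path) ----------------------
# logits: (N, K); targets: integer class index vector (0-based).
# Returns mean loss and d(loss)/d(logits).

loss_and_grad <- function(logits, targets, loss = c("cross_entropy", "label_smoothing"),
                          epsilon = 0.1) {
  loss <- match.arg(loss)
  n <- nrow(logits); k <- ncol(logits)
  p <- softmax(logits)
  yt <- matrix(if (loss == "label_smoothing") epsilon / k else 0, n, k)
  hit <- cbind(seq_len(n), targets + 1L)
  yt[hit] <- yt[hit] + (if (loss == "label_smoothing") 1 - epsilon else 1)
  value <- -mean(rowSums(yt * log(pmax(p, PROB_FLOOR))))
  list(value = value, grad = (p - yt) / n)
}

# Distillation: gradient of alpha*T^2*KL(teacher_T || student_T) + (1-alpha)*CE.
distill_loss_and_grad <- function(student_logits, teacher_logits, targets, spec) {
  n <- nrow(student_logits); k <- ncol(student_logits)
  ps_t <- softmax(student_logits / spec$T)
  pt_t <- softmax(teacher_logits / spec$T)
  soft <- mean(vapply(seq_len(n), function(i) kl_div(pt_t[i, ], ps_t[i, ]), numeric(1)))
  gs <- spec$T * (ps_t - pt_t) / n          # d(T^2 * KL)/d(student logits)
  ps <- softmax(student_logits)
  yh <- matrix(0, n, k); yh[cbind(seq_len(n), targets + 1L)] <- 1
  hard <- -mean(log(pmax(ps[cbind(seq_len(n), targets + 1L)], PROB_FLOOR)))
  gh <- (ps - yh) / n
  list(value = spec$alpha * spec$T^2 * soft + (1 - spec$alpha) * hard,
       grad = spec$alpha * gs + (1 - spec$alpha) * gh)
}
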