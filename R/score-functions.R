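#' Embedding score functions
#'
#' The four triple score functions used by the embedding link-prediction
#' models. For the translational models (TransE, RotatE) the returned value
#' is a distance -- lower means more plausible; the uniform model API used by
#' ranking exposes plausibility as the negated distance. For the semantic
#' matching models (DistMult, ComplEx) higher is more plausible.
#'
#' \describe{
#'   \item{TransE}{\eqn{s(h,r,t) = \|h + r - t\|_p}, real vectors.}
#'   \item{RotatE}{\eqn{s(h,r,t) = \|h \circ r - t\|}, complex vectors with
#'     unit-modulus relation entries (\eqn{\circ} is the Hadamard product);
#'     each relation entry rotates one coordinate of the head.}
#'   \item{DistMult}{\eqn{s(h,r,t) = h^\top \mathrm{diag}(r)\, t}, a
#'     trilinear product, symmetric in \eqn{h} and \eqn{t}.}
#'   \item{ComplEx}{\eqn{s(h,r,t) = \mathrm{Re}(h^\top \mathrm{diag}(r)
#'     \bar t)}, the real part of the Hermitian trilinear form; asymmetric in
#'     general.}
#' }
#'
#' @param h,r,t embedding vectors of equal dimension (complex for
#'   [score_rotate()] and [score_complex()]).
#' @param p norm order for TransE, 1 or 2.
#' @return a single numeric score.
#' @name score_functions
NULL

.check_dim <- function(h, r, t) {
  if (length(h) != length(r) || length(h) != length(t))
    stop("embedding dimension mismatch")
}

#' @rdname score_functions
#' @export
score_transe <- function(h, r, t, p = 2) {
  .check_dim(h, r, t)
  if (!p %in% c(1, 2)) stop("norm order p must be 1 or 2")
  d <- h + r - t
  if (p == 1) sum(abs(d)) else sqrt(sum(d^2))
}

#' @rdname score_functions
#' @export
score_rotate <- function(h, r, t) {
  .check_dim(h, r, t)
  if (any(abs(Mod(r) - 1) > 1e-6))
    stop("RotatE relation entries must have unit modulus")
  sqrt(sum(Mod(h * r - t)^2))
}

#' @rdname score_functions
#' @export
score_distmult <- function(h, r, t) {
  .check_dim(h, r, t)
  sum(h * r * t)
}

#' @rdname score_functions
#' @export
score_complex <- function(h, r, t) {
  .check_dim(h, r, t)
  Re(sum(h * r * Conj(t)))
}

# ---- batched forms used by training/ranking (rows = instances) -------------

.batch_transe <- function(H, R, T, p = 2) {
  D <- H + R - T
  if (p == 1) rowSums(abs(D)) else sqrt(rowSums(D^2))
}

.batch_rotate <- function(Hre, Him, Cos, Sin, Tre, Tim) {
  # h*r with r = cos + i sin
  Cre <- Hre * Cos - Him * Sin - Tre
  Cim <- Hre * Sin + Him * Cos - Tim
  sqrt(rowSums(Cre^2 + Cim^2))
}

.batch_distmult <- function(H, R, T) rowSums(H * R * T)

.batch_complex <- function(Hre, Him, Rre, Rim, Tre, Tim) {
  # Re(h r conj(t)) = (HreRre - HimRim)Tre + (HreRim + HimRre)Tim
  rowSums((Hre * Rre - Him * Rim) * Tre + (Hre * Rim + Him * Rre) * Tim)
}
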