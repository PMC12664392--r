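#' @include structure.R
NULL

#' Optimal rigid superposition of paired coordinate sets (Kabsch)
#'
#' Least-squares rigid alignment: both point sets are centred, the optimal
#' rotation is obtained from the SVD of the covariance matrix, and a
#' reflection-only solution is corrected by flipping the sign of the
#' smallest singular vector so the returned rotation is proper
#' (determinant +1).
#'
#' @param P,Q Numeric matrices (n x 3) of paired coordinates; \code{P} is
#'   rotated onto \code{Q}. At least three non-collinear pairs.
#' @return List with \code{rotation} (3 x 3), \code{translation} (length 3;
#'   the transform is \code{P \%*\% rotation + translation}), and
#'   \code{rmsd} in the coordinate units.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q))
  if (nrow(P) < 3)
    stop("at least three paired atoms are required for superposition")
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  Pr <- P0 %*% R
  rmsd <- sqrt(mean(rowSums((Pr - Q0)^2)))
  list(rotation = R, translation = as.numeric(cQ - cP %*% R), rmsd = rmsd)
}

#' Superposition RMSD between two structures
#'
#' Pairs atoms by author residue number (and atom name) between one chain of
#' each structure, removes residues unmodelled on either side, performs a
#' Kabsch superposition and returns the RMSD. The default pairs C-alpha
#' atoms only; \code{atomNames = NULL} pairs all shared atom names per
#' residue (all-atom RMSD).
#'
#' @param a,b \linkS4class{Structure} objects.
#' @param chainA,chainB Chain to take from each structure; default the first
#'   chain present.
#' @param atomNames Atom names to pair (default \code{"CA"}); \code{NULL}
#'   for all shared atoms.
#' @return List with \code{rmsd} (Angstrom), \code{nPaired}, and the
#'   \code{rotation}/\code{translation} mapping a onto b.
#' @examples
#' s <- toyStructure("mini_interface")
#' superposeRmsd(s, s, chainA = "A", chainB = "A")$rmsd   # 0
#' @export
superposeRmsd <- function(a, b, chainA = NULL, chainB = NULL,
                          atomNames = "CA") {
  stopifnot(is(a, "Structure"), is(b, "Structure"))
  ta <- atoms(a); tb <- atoms(b)
  if (is.null(chainA)) chainA <- ta$chain[1]
  if (is.null(chainB)) chainB <- tb$chain[1]
  ta <- ta[ta$chain == chainA, , drop = FALSE]
  tb <- tb[tb$chain == chainB, , drop = FALSE]
  if (nrow(ta) == 0 || nrow(tb) == 0)
    stop("selected chain is empty")
  if (!is.null(atomNames)) {
    ta <- ta[ta$elety %in% atomNames, , drop = FALSE]
    tb <- tb[tb$elety %in% atomNames, , drop = FALSE]
  }
  keyA <- paste(ta$resno, ta$elety, sep = "\r")
  keyB <- paste(tb$resno, tb$elety, sep = "\r")
  if (anyDuplicated(keyA) || anyDuplicated(keyB))
    stop("duplicated residue number / atom name within a chain; cannot pair")
  common <- intersect(keyA, keyB)
  if (length(common) < 3)
    stop("fewer than three paired atoms; check chain mapping and numbering")
  ia <- match(common, keyA); ib <- match(common, keyB)
  k <- kabsch(cbind(ta$x, ta$y, ta$z)[ia, , drop = FALSE],
              cbind(tb$x, tb$y, tb$z)[ib, , drop = FALSE])
  list(rmsd = k$rmsd, nPaired = length(common),
       rotation = k$rotation, translation = k$translation)
}
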