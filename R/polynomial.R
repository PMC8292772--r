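# Exact sparse multivariate polynomial arithmetic over a fixed alphabet of
# indeterminates, sufficient for differential-algebra elimination on the
# two-species gLV system.  Coefficients are small integers (exactly
# representable as doubles); monomials are exponent vectors.
#
# Alphabet:
#   x          observed relative abundance of species 1
#   xp, xpp    its first and second time derivatives
#   r1, r2     per-capita growth rates
#   b11..b22   interaction rates beta_{i,j}
#   s          a free scalar symbol (used for the B -> s*B substitution)

.POLY_VARS <- c("x", "xp", "xpp", "r1", "r2", "b11", "b12", "b21", "b22", "s")

.pNew <- function(coef, expo) {
  structure(list(coef = coef, expo = expo), class = "glvpoly")
}

pZero <- function() .pNew(numeric(0), matrix(0L, 0, length(.POLY_VARS)))

pConst <- function(a) {
  if (a == 0) return(pZero())
  .pNew(as.numeric(a), matrix(0L, 1, length(.POLY_VARS)))
}

pVar <- function(name) {
  i <- match(name, .POLY_VARS)
  if (is.na(i)) stop("unknown indeterminate: ", name)
  e <- matrix(0L, 1, length(.POLY_VARS))
  e[1, i] <- 1L
  .pNew(1, e)
}

# combine duplicate monomials, drop zero terms, sort for a canonical form
pNormalize <- function(p) {
  if (length(p$coef) == 0) return(p)
  key <- apply(p$expo, 1, paste, collapse = ",")
  coef <- rowsum(p$coef, key)
  keys <- rownames(coef)
  coef <- as.numeric(coef)
  keep <- coef != 0
  if (!any(keep)) return(pZero())
  coef <- coef[keep]
  keys <- keys[keep]
  expo <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  ord <- do.call(order, c(as.data.frame(expo), list(decreasing = TRUE)))
  .pNew(coef[ord], expo[ord, , drop = FALSE])
}

pAdd <- function(p, q) {
  pNormalize(.pNew(c(p$coef, q$coef), rbind(p$expo, q$expo)))
}

pNeg <- function(p) .pNew(-p$coef, p$expo)

pSub <- function(p, q) pAdd(p, pNeg(q))

pMul <- function(p, q) {
  np <- length(p$coef); nq <- length(q$coef)
  if (np == 0 || nq == 0) return(pZero())
  ip <- rep(seq_len(np), each = nq)
  iq <- rep(seq_len(nq), times = np)
  pNormalize(.pNew(p$coef[ip] * q$coef[iq],
                   p$expo[ip, , drop = FALSE] + q$expo[iq, , drop = FALSE]))
}

pScale <- function(p, a) {
  if (a == 0) return(pZero())
  .pNew(p$coef * a, p$expo)
}

pPow <- function(p, k) {
  out <- pConst(1)
  for (i in seq_len(k)) out <- pMul(out, p)
  out
}

# sum of polynomials / linear combination helpers used by the derivation
pSum <- function(...) Reduce(pAdd, list(...), pZero())

# formal partial derivative with respect to one indeterminate
pDeriv <- function(p, name) {
  i <- match(name, .POLY_VARS)
  if (length(p$coef) == 0) return(p)
  k <- p$expo[, i]
  keep <- k > 0
  if (!any(keep)) return(pZero())
  coef <- p$coef[keep] * k[keep]
  expo <- p$expo[keep, , drop = FALSE]
  expo[, i] <- expo[, i] - 1L
  pNormalize(.pNew(coef, expo))
}

# total time derivative along trajectories: d/dt x = xp, d/dt xp = xpp,
# parameters constant
pDotT <- function(p) {
  pAdd(pMul(pDeriv(p, "x"), pVar("xp")),
       pMul(pDeriv(p, "xp"), pVar("xpp")))
}

pIsZero <- function(p, tol = 0) {
  p <- pNormalize(p)
  length(p$coef) == 0 || all(abs(p$coef) <= tol)
}

pEqual <- function(p, q) pIsZero(pSub(p, q))

# evaluate at a named numeric point; unset indeterminates default to 1
pEval <- function(p, values) {
  v <- setNames(rep(1, length(.POLY_VARS)), .POLY_VARS)
  v[names(values)] <- values
  if (length(p$coef) == 0) return(0)
  sum(p$coef * apply(p$expo, 1, function(e) prod(v^e)))
}

# substitute beta_{i,j} -> s * beta_{i,j}: each monomial picks up s^(total
# degree in the four interaction symbols)
pScaleBeta <- function(p) {
  if (length(p$coef) == 0) return(p)
  bcols <- match(c("b11", "b12", "b21", "b22"), .POLY_VARS)
  scol <- match("s", .POLY_VARS)
  expo <- p$expo
  expo[, scol] <- expo[, scol] + as.integer(rowSums(expo[, bcols, drop = FALSE]))
  pNormalize(.pNew(p$coef, expo))
}

# total degree in the interaction symbols (NA if inhomogeneous)
pBetaDegree <- function(p) {
  if (length(p$coef) == 0) return(0L)
  bcols <- match(c("b11", "b12", "b21", "b22"), .POLY_VARS)
  d <- unique(as.integer(rowSums(p$expo[, bcols, drop = FALSE])))
  if (length(d) == 1L) d else NA_integer_
}

pToString <- function(p) {
  p <- pNormalize(p)
  if (length(p$coef) == 0) return("0")
  terms <- vapply(seq_along(p$coef), function(i) {
    e <- p$expo[i, ]
    vars <- .POLY_VARS[e > 0]
    pows <- e[e > 0]
    mono <- paste(ifelse(pows == 1, vars, paste0(vars, "^", pows)),
                  collapse = "*")
    a <- p$coef[i]
    if (mono == "") return(format(a))
    if (a == 1) mono
    else if (a == -1) paste0("-", mono)
    else paste0(format(a), "*", mono)
  }, character(1))
  out <- terms[1]
  for (t in terms[-1]) {
    out <- if (startsWith(t, "-")) paste0(out, " - ", substring(t, 2))
           else paste0(out, " + ", t)
  }
  out
}

#' @export
print.glvpoly <- function(x, ...) {
  cat(pToString(x), "\n")
  invisible(x)
}
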