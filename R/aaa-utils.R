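#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim prcomp setNames aggregate
#' @importFrom utils write.table head
NULL

# Residue key: "chain:resno" or "chain:resno:icode" when an insertion code is set.
res_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == "" | icode == " ", "", icode)
  ifelse(icode == "",
         paste(chain, resno, sep = ":"),
         paste(chain, resno, icode, sep = ":"))
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap an angle in degrees into [0, 360).
wrap360 <- function(x) ((x %% 360) + 360) %% 360

# Circular mean of angles in degrees.
circ_mean_deg <- function(x) {
  r <- deg2rad(x)
  wrap360(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

# Smallest absolute circular difference in degrees.
circ_diff_deg <- function(a, b) {
  d <- wrap360(a - b)
  pmin(d, 360 - d)
}

# All pairwise Euclidean distances between rows of two n x 3 matrices.
cross_dist <- function(xa, xb) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) -
    2 * (xa %*% t(xb))
  d2[d2 < 0] <- 0
  sqrt(d2)
}

THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

ONE_TO_THREE <- setNames(names(THREE_TO_ONE), unname(THREE_TO_ONE))

aa3to1 <- function(x) {
  out <- unname(THREE_TO_ONE[toupper(x)])
  out[is.na(out)] <- "X"
  out
}

aa1to3 <- function(x) {
  out <- unname(ONE_TO_THREE[toupper(x)])
  if (any(is.na(out))) stop("unknown one-letter amino-acid code: ",
                            paste(x[is.na(out)], collapse = ", "))
  out
}
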