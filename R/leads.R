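#' Standard 12-lead geometry
#'
#' The synthetic generator projects a 3-D cardiac dipole onto the 12 standard
#' leads. Leads I, II and V1-V6 carry independent lead vectors (the classical
#' Dower transfer matrix); the remaining limb leads are linear combinations:
#' III = II - I, aVR = -(I + II)/2, aVL = I - II/2, aVF = II - I/2.
#'
#' @return `lead_names_12()`: the 12 lead labels in conventional order.
#'   `dower_matrix()`: an 8 x 3 matrix of lead vectors for I, II, V1-V6.
#'   `expand_to_12_leads()`: a 12 x n matrix given an 8 x n matrix of the
#'   independent leads.
#' @export
lead_names_12 <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' @rdname lead_names_12
#' @export
lead_names_8 <- function() c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

limb_lead_names <- function() c("I", "II", "III", "aVR", "aVL", "aVF")

chest_lead_names <- function() c("V1", "V2", "V3", "V4", "V5", "V6")

#' @rdname lead_names_12
#' @export
dower_matrix <- function() {
  m <- rbind(
    I  = c( 0.632, -0.235,  0.059),
    II = c( 0.235,  1.066, -0.132),
    V1 = c(-0.515,  0.157, -0.917),
    V2 = c( 0.044,  0.164, -1.387),
    V3 = c( 0.882,  0.098, -1.277),
    V4 = c( 1.213,  0.127, -0.601),
    V5 = c( 1.125,  0.127, -0.086),
    V6 = c( 0.831,  0.076,  0.230)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' @rdname lead_names_12
#' @param eight numeric matrix, 8 rows in the order I, II, V1-V6.
#' @export
expand_to_12_leads <- function(eight) {
  stopifnot(nrow(eight) == 8)
  I <- eight[1, ]; II <- eight[2, ]
  out <- rbind(
    I, II,
    III = II - I,
    aVR = -(I + II) / 2,
    aVL = I - II / 2,
    aVF = II - I / 2,
    eight[3:8, , drop = FALSE]
  )
  rownames(out) <- lead_names_12()
  out
}

# Rotate a 3-vector about the z (anteroposterior) axis by `deg` degrees.
rotate_z <- function(v, deg) {
  th <- deg * pi / 180
  r <- matrix(c(cos(th), -sin(th), 0,
                sin(th),  cos(th), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  as.numeric(r %*% v)
}
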