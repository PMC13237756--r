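# Default 65-electrode montage: the 64 recorded channels of a standard
# 64-channel cap plus the recovered online reference FCz, on an idealized
# spherical head. Positions are constructed from the extended 10-20 scheme:
# midline electrodes at 18-degree steps along the nasion-inion great circle,
# an outer ring at 72 degrees polar angle through Fp1/2, F7/8, T7/8, P7/8,
# O1/2 (with 10-10 intermediates), a lower ring at 90 degrees for the
# "9/10" electrodes, and intermediate rows by great-circle interpolation
# between the midline anchor and the ring electrode of the same row.

slerp <- function(p0, p1, t) {
  om <- acos(pmin(1, pmax(-1, sum(p0 * p1))))
  if (om < 1e-12) return(matrix(rep(p0, length(t)), ncol = 3, byrow = TRUE))
  s <- sin(om)
  out <- t(vapply(t, function(tt)
    (sin((1 - tt) * om) * p0 + sin(tt * om) * p1) / s, numeric(3)))
  out / sqrt(rowSums(out^2))
}

defaultMontageTable <- function() {
  pt <- function(theta, phi) drop(sphericalToCartesian(theta, phi))
  # midline anchors (theta from vertex; phi 90 = anterior, -90 = posterior)
  mid <- list(Fpz = pt(72, 90), AFz = pt(54, 90), Fz = pt(36, 90),
              FCz = pt(18, 90), Cz = pt(0, 0), CPz = pt(18, -90),
              Pz = pt(36, -90), POz = pt(54, -90), Oz = pt(72, -90))
  # outer ring, theta = 72; alpha = arc from the front midline point
  ringAlpha <- c(Fp = 18, AF = 36, F = 54, FT = 72, T = 90, TP = 108,
                 P = 126, PO = 144, O = 162)
  ringPt <- function(alpha, side) {         # side +1 left, -1 right
    phi <- 90 + side * alpha
    if (phi > 180) phi <- phi - 360
    pt(72, phi)
  }
  lowerPt <- function(alpha, side) {        # "9/10" ring at theta = 90
    phi <- 90 + side * alpha
    if (phi > 180) phi <- phi - 360
    pt(90, phi)
  }
  rows <- list()
  add <- function(label, p) rows[[label]] <<- p

  ringLab <- list(Fp = c("Fp1", "Fp2"), AF = c("AF7", "AF8"),
                  F = c("F7", "F8"), FT = c("FT7", "FT8"),
                  T = c("T7", "T8"), TP = c("TP7", "TP8"),
                  P = c("P7", "P8"), PO = c("PO7", "PO8"),
                  O = c("O1", "O2"))
  for (fam in names(ringLab)) {
    add(ringLab[[fam]][1], ringPt(ringAlpha[[fam]], +1))
    add(ringLab[[fam]][2], ringPt(ringAlpha[[fam]], -1))
  }
  for (fam in c("FT", "TP", "PO")) {
    add(paste0(fam, "9"),  lowerPt(ringAlpha[[fam]], +1))
    add(paste0(fam, "10"), lowerPt(ringAlpha[[fam]], -1))
  }
  # intermediate electrodes: slerp between midline anchor and ring electrode
  inner <- function(midLab, fam, labsL, labsR, tfrac) {
    pm <- mid[[midLab]]
    pl <- rows[[ringLab[[fam]][1]]]; pr <- rows[[ringLab[[fam]][2]]]
    sl <- slerp(pm, pl, tfrac); sr <- slerp(pm, pr, tfrac)
    for (j in seq_along(labsL)) { add(labsL[j], sl[j, ]); add(labsR[j], sr[j, ]) }
  }
  inner("Fz",  "F",  c("F1", "F3", "F5"),    c("F2", "F4", "F6"),
        c(0.25, 0.5, 0.75))
  inner("FCz", "FT", c("FC1", "FC3", "FC5"), c("FC2", "FC4", "FC6"),
        c(0.25, 0.5, 0.75))
  inner("Cz",  "T",  c("C1", "C3", "C5"),    c("C2", "C4", "C6"),
        c(0.25, 0.5, 0.75))
  inner("CPz", "TP", c("CP1", "CP3", "CP5"), c("CP2", "CP4", "CP6"),
        c(0.25, 0.5, 0.75))
  inner("Pz",  "P",  c("P1", "P3", "P5"),    c("P2", "P4", "P6"),
        c(0.25, 0.5, 0.75))
  inner("AFz", "AF", "AF3", "AF4", 0.5)
  inner("POz", "PO", "PO3", "PO4", 0.5)
  for (lab in c("Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz"))
    add(lab, mid[[lab]])

  labs <- names(rows)
  co <- do.call(rbind, rows)
  ang <- cartesianToSpherical(co)
  tab <- data.frame(label = labs, theta_deg = ang$theta_deg,
                    phi_deg = ang$phi_deg, stringsAsFactors = FALSE)
  tab[order(tab$label, method = "radix"), , drop = FALSE]  # locale-stable
}

#' Build the default 65-electrode layout
#'
#' Deterministic extended 10-20 montage of the 64 recorded channels of a
#' standard 64-channel cap plus the recovered online reference FCz, on the
#' unit sphere. Identical across calls.
#'
#' @return an \linkS4class{ElectrodeLayout} with 65 electrodes
#' @export
buildDefaultLayout <- function() {
  tab <- defaultMontageTable()
  electrodeLayout(tab$label, tab$theta_deg, tab$phi_deg)
}

#' Read a montage file
#'
#' Delimited text with columns \code{label}, \code{theta_deg},
#' \code{phi_deg}. Angle ranges and label uniqueness are validated.
#'
#' @param path file path (tab- or comma-delimited; inferred from content)
#' @return an \linkS4class{ElectrodeLayout}
#' @export
readMontage <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("label", "theta_deg", "phi_deg")
  if (!all(need %in% names(tab)))
    stop("montage file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  electrodeLayout(tab$label, tab$theta_deg, tab$phi_deg)
}

#' Write a montage file
#'
#' @param layout an \linkS4class{ElectrodeLayout}
#' @param path output path (tab-delimited)
#' @export
writeMontage <- function(layout, path) {
  utils::write.table(sphericalAngles(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
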