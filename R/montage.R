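# Electrode montage and analysis grids.

#' Standard 64-channel 10-20/10-10 montage
#'
#' Channel names of the 64-electrode cap used by the synthesizer. Contains
#' every channel referenced by the analysis grids ([erp_grids()]).
#'
#' @return Character vector of 64 channel names.
#' @export
montage_64 <- function() {
  c("Fp1", "Fz", "F3", "F7", "FT9", "FC5", "FC1", "C3", "T7", "TP9",
    "CP5", "CP1", "Pz", "P3", "P7", "O1", "Oz", "O2", "P4", "P8",
    "TP10", "CP6", "CP2", "Cz", "C4", "T8", "FT10", "FC6", "FC2", "F4",
    "F8", "Fp2", "AF7", "AF3", "AFz", "F1", "F5", "FT7", "FC3", "C1",
    "C5", "TP7", "CP3", "P1", "P5", "PO7", "PO3", "POz", "PO4", "PO8",
    "P6", "P2", "CPz", "CP4", "TP8", "C6", "C2", "FC4", "FT8", "F6",
    "AF8", "AF4", "F2", "FCz")
}

#' Electrode grids used for component measurement
#'
#' Frontocentral grid for the P1-N1-P2 complex, right-frontal/central grid
#' for the MMN, and centroparietal grid for the P3b.
#'
#' @return Named list of character vectors (`p1`, `mmn`, `p3b`). The `p1`
#'   grid is also used for N1 and P2 and for P1-anchored latency alignment.
#' @export
erp_grids <- function() {
  list(
    p1  = c("Fz", "F1", "F2", "FCz", "FC1", "FC2"),
    mmn = c("AF4", "AF8", "Fz", "F2", "F4", "F6", "FCz", "FC2", "FC4",
            "FT8", "Cz", "C2", "C4", "C6", "T8"),
    p3b = c("CP1", "CPz", "CP2", "P1", "Pz", "P2")
  )
}

# Topography weight vector for a component over a montage. Weights are 1 (or
# rescaled so the grid mean is exactly 1) on the component's source channels
# and a compensating negative constant on channels outside every analysis
# grid, so each topography sums to zero across the montage and the average
# reference leaves grid measurements unchanged.
#
# The deviance components (MMN) deliberately avoid channels shared with the
# p1 grid so that early-component peak windows on target trials are not
# contaminated; the remaining grid channels are up-weighted so the grid mean
# still equals the nominal amplitude.
component_topography <- function(component, montage = montage_64(),
                                 grids = erp_grids()) {
  w <- stats::setNames(numeric(length(montage)), montage)
  grid_all <- unique(unlist(grids))
  free <- setdiff(montage, grid_all)
  src <- switch(component,
    P1 = , N1 = , P2 = grids$p1,
    MMN = setdiff(grids$mmn, grids$p1),
    P3b = grids$p3b,
    stop("unknown component: ", component)
  )
  missing <- setdiff(src, montage)
  if (length(missing)) {
    stop("montage lacks channels: ", paste(missing, collapse = ", "))
  }
  grid <- switch(component, P1 = , N1 = , P2 = "p1", MMN = "mmn", P3b = "p3b")
  gch <- grids[[grid]]
  # grid mean of the weights must be exactly 1
  w[src] <- length(gch) / length(src)
  w[free] <- -sum(w) / length(free)
  w
}
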