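#' Electrode montages
#'
#' An `eeg_montage` is a tibble with one row per electrode and columns
#' `label`, `x`, `y`, `z` (unit-sphere coordinates: +x right, +y anterior,
#' +z superior) and `is_mastoid`. Exactly two electrodes are designated
#' mastoids; they sit below the equator of the sphere and serve as the
#' reference pair for [rereference_mastoid()].
#'
#' `generate_montage()` is a pure function: the same `n_channels` always
#' yields the identical montage. With `n_channels = 64` the standard
#' extended 10-20 labelling is used; other channel counts get generic
#' labels (`E1`, `E2`, ...) laid out on a spherical Fibonacci lattice over
#' the upper hemisphere plus two mastoids.
#'
#' @param n_channels Number of electrodes (>= 4, including the 2 mastoids).
#' @return An `eeg_montage` tibble with `n_channels` rows.
#' @examples
#' m <- generate_montage(64)
#' range(sqrt(m$x^2 + m$y^2 + m$z^2))  # all 1
#' @export
generate_montage <- function(n_channels = 64) {
  check_scalar_num(n_channels, "n_channels", lower = 4)
  n_channels <- as.integer(n_channels)
  if (n_channels == 64L) {
    tab <- montage_1020_table()
  } else {
    tab <- montage_generic_table(n_channels)
  }
  pos <- place_on_sphere(tab$a, tab$l)
  out <- tibble::tibble(
    label = tab$label,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    is_mastoid = tab$is_mastoid
  )
  stopifnot(!anyDuplicated(out$label), sum(out$is_mastoid) == 2L)
  class(out) <- c("eeg_montage", class(out))
  out
}

# 10-20 style layout parameterized by an anterior-posterior fraction `a`
# (-1 nasion .. +1 inion) and a signed lateral fraction `l` (- left).
montage_1020_table <- function() {
  rows <- list(
    c(Fp1 = -0.25, Fpz = 0, Fp2 = 0.25),
    c(AF7 = -0.75, AF3 = -0.4, AFz = 0, AF4 = 0.4, AF8 = 0.75),
    c(F7 = -1, F5 = -0.75, F3 = -0.5, F1 = -0.25, Fz = 0,
      F2 = 0.25, F4 = 0.5, F6 = 0.75, F8 = 1),
    c(FT7 = -1, FC5 = -0.75, FC3 = -0.5, FC1 = -0.25, FCz = 0,
      FC2 = 0.25, FC4 = 0.5, FC6 = 0.75, FT8 = 1),
    c(T7 = -1, C5 = -0.75, C3 = -0.5, C1 = -0.25, Cz = 0,
      C2 = 0.25, C4 = 0.5, C6 = 0.75, T8 = 1),
    c(TP7 = -1, CP5 = -0.75, CP3 = -0.5, CP1 = -0.25, CPz = 0,
      CP2 = 0.25, CP4 = 0.5, CP6 = 0.75, TP8 = 1),
    c(P7 = -1, P5 = -0.75, P3 = -0.5, P1 = -0.25, Pz = 0,
      P2 = 0.25, P4 = 0.5, P6 = 0.75, P8 = 1),
    c(PO7 = -0.75, PO3 = -0.4, POz = 0, PO4 = 0.4, PO8 = 0.75),
    c(O1 = -0.25, Oz = 0, O2 = 0.25),
    c(Iz = 0)
  )
  a_rows <- c(-0.8, -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.8, 1)
  lab <- unlist(lapply(rows, names))
  l <- unname(unlist(rows))
  a <- rep(a_rows, vapply(rows, length, 1L))
  lab <- c(lab, "M1", "M2")
  a <- c(a, 0.1, 0.1)
  l <- c(l, -1.15, 1.15)
  list(label = lab, a = a, l = l,
       is_mastoid = lab %in% c("M1", "M2"))
}

montage_generic_table <- function(n) {
  n_scalp <- n - 2L
  i <- seq_len(n_scalp)
  # Fibonacci lattice over the upper hemisphere, expressed as (a, l)
  r <- sqrt((i - 0.5) / n_scalp) * 0.95
  phi <- (i - 1) * pi * (3 - sqrt(5))
  a <- -r * cos(phi)
  l <- r * sin(phi)
  list(label = c(paste0("E", i), "M1", "M2"),
       a = c(a, 0.1, 0.1),
       l = c(l, -1.15, 1.15),
       is_mastoid = c(rep(FALSE, n_scalp), TRUE, TRUE))
}

place_on_sphere <- function(a, l) {
  r <- sqrt(a^2 + l^2)
  theta <- pmin(r, 1.3) * (pi / 2)    # inclination from the vertex
  dir_l <- ifelse(r > 0, l / r, 0)
  dir_a <- ifelse(r > 0, -a / r, 0)
  cbind(x = sin(theta) * dir_l,
        y = sin(theta) * dir_a,
        z = cos(theta))
}

montage_positions <- function(montage) {
  m <- as.matrix(montage[, c("x", "y", "z")])
  rownames(m) <- montage$label
  m
}

mastoid_labels <- function(montage) montage$label[montage$is_mastoid]

# Unit direction of the left fronto-temporal focus used for the simulated
# P2 topography (midway between F7 and FT7 on the named montage).
montage_left_frontotemporal <- function(montage) {
  pos <- montage_positions(montage)
  if (all(c("F7", "FT7") %in% rownames(pos))) {
    v <- colSums(pos[c("F7", "FT7"), ])
  } else {
    v <- c(-0.85, 0.40, 0.35)
  }
  v / sqrt(sum(v^2))
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels (%s mastoids)\n",
              nrow(x), paste(mastoid_labels(x), collapse = "/")))
  NextMethod()
}

#' Write / read a montage as CSV
#'
#' Plain `label,x,y,z,is_mastoid` CSV round trip.
#'
#' @param montage An `eeg_montage`.
#' @param path File path.
#' @return `read_montage()` returns an `eeg_montage`.
#' @export
write_montage <- function(montage, path) {
  write.csv(as.data.frame(montage), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  out$is_mastoid <- as.logical(out$is_mastoid)
  class(out) <- c("eeg_montage", class(out))
  out
}
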