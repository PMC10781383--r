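#' Band naming for the six-channel multispectral instrument
#'
#' Band centres 450, 555, 660, 720, 750 and 840 nm, aliased Blue, Green,
#' Red, Edge1, Edge2, NIR and B1..B6 in that wavelength order.
#'
#' @export
band_centers <- c(Blue = 450, Green = 555, Red = 660,
                  Edge1 = 720, Edge2 = 750, NIR = 840)

#' @rdname band_centers
#' @export
band_names <- paste0("B", 1:6)

.as_band_vector <- function(bands) {
  b <- as.numeric(bands)
  if (length(b) != 6 || anyNA(b) || any(!is.finite(b))) {
    stop("a band vector has 6 finite entries (450..840 nm)", call. = FALSE)
  }
  names(b) <- names(band_centers)
  b
}

# Guarded division: denominators smaller than 1e-9 in magnitude mask the value.
.safe_div <- function(num, den) {
  out <- num / den
  out[abs(den) < 1e-9] <- NA_real_
  out
}

# Each entry: two closures (as_printed, canonical) of the named band columns
# (matrices n x 6 with columns Blue..NIR), a human-readable formula string per
# mode, and a per-mode flag for invariance to a global reflectance rescaling.
.vi_registry <- local({
  def <- function(printed, canonical = printed,
                  printed_str, canonical_str = printed_str,
                  inv_printed = TRUE, inv_canonical = inv_printed) {
    list(as_printed = printed, canonical = canonical,
         formula = c(as_printed = printed_str, canonical = canonical_str),
         scale_invariant = c(as_printed = inv_printed,
                             canonical = inv_canonical))
  }
  list(
    BGI = def(function(b) .safe_div(b[, "Blue"], b[, "Green"]),
              printed_str = "Blue/Green"),
    CIg = def(function(b) .safe_div(b[, "NIR"], b[, "Green"]) - 1,
              printed_str = "(NIR/Green) - 1"),
    CIre = def(function(b) .safe_div(b[, "NIR"], b[, "Edge1"]) - 1,
               printed_str = "(NIR/Edge1) - 1"),
    CVI = def(function(b) .safe_div(b[, "NIR"] * b[, "Red"], b[, "Blue"]^2),
              function(b) .safe_div(b[, "NIR"] * b[, "Red"], b[, "Green"]^2),
              printed_str = "NIR * Red / Blue^2",
              canonical_str = "NIR * Red / Green^2"),
    Datt = def(function(b) .safe_div(b[, "NIR"] - b[, "Edge1"],
                                     b[, "NIR"] - b[, "Red"]),
               printed_str = "(NIR - Edge1)/(NIR - Red)"),
    GLI = def(function(b) .safe_div(2 * b[, "Green"] - b[, "Red"] - b[, "Blue"],
                                    2 * b[, "Green"] + b[, "Red"] + b[, "Blue"]),
              printed_str = "(2*Green - Red - Blue)/(2*Green + Red + Blue)"),
    GNDVI = def(function(b) .safe_div(b[, "NIR"] - b[, "Green"],
                                      b[, "NIR"] + b[, "Green"]),
                printed_str = "(NIR - Green)/(NIR + Green)"),
    GRNDVI = def(function(b) .safe_div(b[, "NIR"] - b[, "Green"] - b[, "Blue"],
                                       b[, "NIR"] + b[, "Green"] + b[, "Blue"]),
                 function(b) .safe_div(b[, "NIR"] - b[, "Green"] - b[, "Red"],
                                       b[, "NIR"] + b[, "Green"] + b[, "Red"]),
                 printed_str = "(NIR - Green - Blue)/(NIR + Green + Blue)",
                 canonical_str = "(NIR - Green - Red)/(NIR + Green + Red)"),
    LCI = def(function(b) .safe_div(b[, "NIR"] - b[, "Edge1"],
                                    b[, "NIR"] + b[, "Red"]),
              printed_str = "(NIR - Edge1)/(NIR + Red)"),
    mNDVI = def(function(b) .safe_div(b[, "NIR"] - b[, "Red"],
                                      b[, "NIR"] + b[, "Red"] - 2 * b[, "Blue"]),
                printed_str = "(NIR - Red)/(NIR + Red - 2*Blue)"),
    MSR = def(function(b) {
                q <- .safe_div(b[, "NIR"], b[, "Red"])
                .safe_div(q - 1, q + 1)
              },
              function(b) {
                q <- .safe_div(b[, "NIR"], b[, "Red"])
                .safe_div(q - 1, sqrt(pmax(q + 1, 0)))
              },
              printed_str = "((NIR/Red) - 1)/((NIR/Red) + 1)",
              canonical_str = "((NIR/Red) - 1)/sqrt((NIR/Red) + 1)"),
    MSRre = def(function(b) .safe_div(b[, "NIR"] - b[, "Edge1"] - 1,
                                      b[, "NIR"] - b[, "Edge1"] + 1),
                function(b) {
                  q <- .safe_div(b[, "NIR"], b[, "Edge1"])
                  .safe_div(q - 1, sqrt(pmax(q + 1, 0)))
                },
                printed_str = "(NIR - Edge1 - 1)/(NIR - Edge1 + 1)",
                canonical_str = "((NIR/Edge1) - 1)/sqrt((NIR/Edge1) + 1)",
                inv_printed = FALSE, inv_canonical = TRUE),
    MTCI = def(function(b) .safe_div(b[, "Edge2"] - b[, "Edge1"],
                                     b[, "Edge1"] - b[, "Red"]),
               printed_str = "(Edge2 - Edge1)/(Edge1 - Red)"),
    NDRE = def(function(b) .safe_div(b[, "NIR"] - b[, "Edge1"],
                                     b[, "NIR"] + b[, "Edge1"]),
               printed_str = "(NIR - Edge1)/(NIR + Edge1)"),
    NDVI = def(function(b) .safe_div(b[, "NIR"] - b[, "Red"],
                                     b[, "NIR"] + b[, "Red"]),
               printed_str = "(NIR - Red)/(NIR + Red)"),
    NDVIg = def(function(b) .safe_div(b[, "Edge2"] - b[, "Green"],
                                      b[, "Edge2"] + b[, "Green"]),
                printed_str = "(Edge2 - Green)/(Edge2 + Green)"),
    NGRDI = def(function(b) .safe_div(b[, "Green"] - b[, "Red"],
                                      b[, "Green"] + b[, "Red"]),
                printed_str = "(Green - Red)/(Green + Red)"),
    NPCI = def(function(b) .safe_div(b[, "Red"] - b[, "Blue"],
                                     b[, "Red"] + b[, "Blue"]),
               printed_str = "(Red - Blue)/(Red + Blue)"),
    PPR = def(function(b) .safe_div(b[, "Green"] - b[, "Blue"],
                                    b[, "Green"] + b[, "Blue"]),
              printed_str = "(Green - Blue)/(Green + Blue)"),
    PSSR = def(function(b) .safe_div(b[, "NIR"], b[, "Red"]),
               printed_str = "NIR/Red"),
    RDVI = def(function(b) .safe_div(b[, "NIR"] - b[, "Red"],
                                     b[, "NIR"] + b[, "Red"]),
               function(b) .safe_div(b[, "NIR"] - b[, "Red"],
                                     sqrt(pmax(b[, "NIR"] + b[, "Red"], 0))),
               printed_str = "(NIR - Red)/(NIR + Red)",
               canonical_str = "(NIR - Red)/sqrt(NIR + Red)",
               inv_printed = TRUE, inv_canonical = FALSE),
    RENDVI = def(function(b) .safe_div(b[, "Edge2"] - b[, "Edge1"],
                                       b[, "Edge2"] + b[, "Edge1"]),
                 printed_str = "(Edge2 - Edge1)/(Edge2 + Edge1)"),
    SIPI2 = def(function(b) .safe_div(b[, "NIR"] - b[, "Blue"],
                                      b[, "NIR"] - b[, "Red"]),
                printed_str = "(NIR - Blue)/(NIR - Red)"),
    SR450_660 = def(function(b) .safe_div(b[, "Blue"], b[, "Red"]),
                    printed_str = "Blue/Red"),
    SR750_555 = def(function(b) .safe_div(b[, "Edge2"], b[, "Green"]),
                    printed_str = "Edge2/Green"),
    VOG1 = def(function(b) .safe_div(b[, "Edge2"], b[, "Edge1"]),
               printed_str = "Edge2/Edge1")
  )
})

#' Vegetation-index registry
#'
#' Twenty-six published vegetation indices computable from the six bands.
#' Two formula modes exist for every index: `"as_printed"` follows the
#' source table literally (including its idiosyncratic MSR, MSRre, RDVI,
#' CVI and GRNDVI forms), `"canonical"` substitutes the originally
#' published formulations where the two differ. The default everywhere is
#' `"as_printed"`.
#'
#' @param mode Formula mode, `"as_printed"` or `"canonical"`.
#' @return `vi_names()`: character vector of the 26 abbreviations.
#'   `vi_registry()`: data.frame with name, formula and scale-invariance
#'   flag for the chosen mode.
#' @export
vi_names <- function() names(.vi_registry)

#' @rdname vi_names
#' @export
vi_registry <- function(mode = c("as_printed", "canonical")) {
  mode <- match.arg(mode)
  data.frame(
    name = names(.vi_registry),
    formula = vapply(.vi_registry, function(e) unname(e$formula[mode]), ""),
    scale_invariant = vapply(.vi_registry,
                             function(e) unname(e$scale_invariant[mode]),
                             logical(1)),
    mode = mode,
    row.names = NULL
  )
}

#' @rdname vi_names
#' @param path YAML file to write the registry to.
#' @export
write_vi_registry <- function(path, mode = c("as_printed", "canonical")) {
  mode <- match.arg(mode)
  reg <- vi_registry(mode)
  yaml::write_yaml(
    lapply(seq_len(nrow(reg)), function(i) as.list(reg[i, ])), path)
  invisible(path)
}

#' Compute a vegetation index
#'
#' @param name One of [vi_names()].
#' @param bands Either a length-6 numeric vector (Blue, Green, Red, Edge1,
#'   Edge2, NIR reflectances, i.e. 450..840 nm) or an n x 6 matrix of such
#'   rows.
#' @param mode Formula mode, see [vi_registry()].
#' @return Numeric value(s); `NA` where a denominator magnitude falls
#'   below 1e-9 (masked rather than infinite).
#' @examples
#' compute_vi("NDVI", c(0.05, 0.1, 0.1, 0.3, 0.45, 0.5))
#' @export
compute_vi <- function(name, bands, mode = c("as_printed", "canonical")) {
  mode <- match.arg(mode)
  if (!name %in% names(.vi_registry)) {
    stop("unknown vegetation index: ", name, call. = FALSE)
  }
  if (is.null(dim(bands))) {
    b <- matrix(.as_band_vector(bands), nrow = 1,
                dimnames = list(NULL, names(band_centers)))
    drop <- TRUE
  } else {
    b <- as.matrix(bands)
    if (ncol(b) != 6) stop("band matrix needs 6 columns", call. = FALSE)
    colnames(b) <- names(band_centers)
    drop <- FALSE
  }
  out <- .vi_registry[[name]][[mode]](b)
  if (drop) out[[1]] else out
}
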