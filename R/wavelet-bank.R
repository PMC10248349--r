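# Standard published low-pass wavelet coefficient tables (orthonormal
# convention, sum(l) = sqrt(2)). Orthogonal entries are the analysis low-pass
# l (self-dual). Biorthogonal entries carry the analysis low-pass l and the
# dual (synthesis) low-pass lt, zero-padded to a common even length and
# aligned so the dual delta identity sum_k l_k lt_{k+2m} = delta(m) holds.
# The reverse-biorthogonal family swaps the roles of l and lt.
.orthLowPass <- list(
  "haar" = c(0.70710678118654757, 0.70710678118654757),
  "db2" = c(0.48296291314453416, 0.83651630373780794, 0.22414386804201339, -0.12940952255126037),
  "db3" = c(0.33267055295008263, 0.80689150931109255, 0.45987750211849154, -0.13501102001025458, -0.085441273882026658, 0.035226291885709533),
  "db4" = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892, -0.027983769416859854, -0.18703481171909309, 0.030841381835560764, 0.032883011666885197, -0.010597401785069032),
  "db5" = c(0.16010239797419293, 0.60382926979718965, 0.72430852843777294, 0.13842814590132074, -0.24229488706638203, -0.032244869584638375, 0.077571493840045719, -0.0062414902127982744, -0.012580751999081999, 0.0033357252854737712),
  "db6" = c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536, 0.31525035170919763, -0.22626469396543983, -0.12976686756726194, 0.097501605587323043, 0.027522865530305727, -0.03158203931748603, 0.00055384220116149613, 0.0047772575109455108, -0.0010773010853084796),
  "db7" = c(0.077852054085009184, 0.39653931948191729, 0.72913209084623509, 0.46978228740519312, -0.14390600392856498, -0.22403618499387498, 0.071309219266830259, 0.080612609151083078, -0.038029936935014413, -0.016574541630666881, 0.01255099855609984, 0.00042957797292136651, -0.0018016407040474908, 0.00035371379997452024),
  "sym2" = c(0.48296291314469025, 0.83651630373746899, 0.22414386804185735, -0.12940952255092145),
  "sym3" = c(0.33267055295095688, 0.80689150931333875, 0.45987750211933132, -0.13501102001039084, -0.085441273882241486, 0.035226291882100656),
  "sym4" = c(0.032223100604042702, -0.012603967262037833, -0.099219543576847216, 0.29785779560527736, 0.80373875180591614, 0.49761866763201545, -0.02963552764599851, -0.075765714789273325),
  "sym5" = c(0.019538882735286728, -0.021101834024758855, -0.17532808990845047, 0.016602105764522319, 0.63397896345821192, 0.72340769040242059, 0.1993975339773936, -0.039134249302383094, 0.029519490925774643, 0.027333068345077982),
  "sym6" = c(-0.007800708325034148, 0.0017677118642428036, 0.044724901770665779, -0.021060292512300564, -0.072637522786462516, 0.3379294217276218, 0.787641141030194, 0.49105594192674662, -0.048311742585632998, -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373),
  "sym7" = c(0.010268176708511255, 0.0040102448715336634, -0.10780823770381774, -0.14004724044296152, 0.28862963175151463, 0.76776431700316405, 0.5361019170917628, 0.017441255086855827, -0.049552834937127255, 0.067892693501372697, 0.03051551316596357, -0.01263630340325193, -0.0010473848886829163, 0.0026818145682578781))

.biorLowPass <- list(
  "1.1" = list(
    l  = c(0.70710678118654757, 0.70710678118654757),
    lt = c(0.70710678118654757, 0.70710678118654757)),
  "2.2" = list(
    l  = c(-0.17677669529663689, 0.35355339059327379, 1.0606601717798212, 0.35355339059327379, -0.17677669529663689, 0),
    lt = c(0, 0.35355339059327379, 0.70710678118654757, 0.35355339059327379, 0, 0)),
  "3.3" = list(
    l  = c(0.066291260736238825, -0.19887378220871649, -0.15467960838455727, 0.99436891104358249, 0.99436891104358249, -0.15467960838455727, -0.19887378220871649, 0.066291260736238825),
    lt = c(0, 0, 0.17677669529663689, 0.5303300858899106, 0.5303300858899106, 0.17677669529663689, 0, 0)),
  "4.4" = list(
    l  = c(0.03782845550726404, -0.023849465019556843, -0.11062440441843718, 0.37740285561283066, 0.85269867900889385, 0.37740285561283066, -0.11062440441843718, -0.023849465019556843, 0.03782845550726404, 0),
    lt = c(0, -0.064538882628697058, -0.040689417609164058, 0.41809227322161724, 0.7884856164055829, 0.41809227322161724, -0.040689417609164058, -0.064538882628697058, 0, 0)))

#' Registry of supported wavelet names
#'
#' The 21 supported wavelets: `haar`, `db2`--`db7`, `sym2`--`sym7`,
#' `bior1.1/2.2/3.3/4.4` and `rbio1.1/2.2/3.3/4.4`. `db1` and `sym1` are
#' accepted as aliases of `haar` when parsing names.
#'
#' @return character vector of wavelet names.
#' @examples
#' availableWavelets()
#' @export
availableWavelets <- function() {
  c("haar", paste0("db", 2:7), paste0("sym", 2:7),
    paste0("bior", c("1.1", "2.2", "3.3", "4.4")),
    paste0("rbio", c("1.1", "2.2", "3.3", "4.4")))
}

#' Create a wavelet specification
#'
#' Either give `family` and `order` separately or a single name such as
#' `"sym6"` or `"bior2.2"` as `family`.
#'
#' @param family family name or full wavelet name.
#' @param order integer scale `S` (orthogonal) or order string such as
#'   `"2.2"` (biorthogonal); ignored when `family` is a full name.
#' @return a [WaveletSpec-class].
#' @examples
#' waveletSpec("sym6")
#' waveletSpec("bior", "2.2")
#' @export
waveletSpec <- function(family, order = NULL) {
  if (is.null(order)) {
    m <- regmatches(family, regexec("^([a-z]+)([0-9.]*)$", family))[[1]]
    if (length(m) != 3L || m[2] == "")
      stop(sprintf("unsupported wavelet '%s'; valid wavelets: %s",
                   family, paste(availableWavelets(), collapse = ", ")))
    family <- m[2]
    order <- if (m[3] == "") "1" else m[3]
  }
  order <- as.character(order)
  # db1/sym1 are the Haar wavelet
  if (family %in% c("db", "sym") && order == "1") {
    family <- "haar"
  }
  obj <- try(new("WaveletSpec", family = family, order = order), silent = TRUE)
  if (inherits(obj, "try-error"))
    stop(sprintf("unsupported wavelet '%s%s'; valid wavelets: %s",
                 family, order, paste(availableWavelets(), collapse = ", ")))
  obj
}

waveletName <- function(spec) {
  if (spec@family == "haar") "haar" else paste0(spec@family, spec@order)
}

#' Build a wavelet filter bank
#'
#' Looks up the standard published low-pass coefficients for the requested
#' wavelet and derives the high-pass filters by the alternating-sign
#' index-reversal (quadrature mirror) recurrence: for a common filter length
#' `2n + 2`, `h_i = (-1)^i lt_{2n+1-i}` and `ht_i = (-1)^i l_{2n+1-i}`
#' (indices from 0). Orthogonal banks are self-dual (`lt = l`), so both
#' recurrences coincide. Coefficients use the orthonormal normalization
#' `sum(l) = sqrt(2)`.
#'
#' @param spec a [WaveletSpec-class], or a wavelet name such as `"sym6"`.
#' @return a [WaveletFilterBank-class].
#' @examples
#' bank <- buildFilterBank("haar")
#' analysisLow(bank)   # (1, 1) / sqrt(2)
#' analysisHigh(bank)  # (1, -1) / sqrt(2)
#' @export
buildFilterBank <- function(spec) {
  if (is.character(spec)) spec <- waveletSpec(spec)
  stopifnot(is(spec, "WaveletSpec"))
  validObject(spec)
  fam <- spec@family
  if (fam %in% c("haar", "db", "sym")) {
    nm <- waveletName(spec)
    l <- .orthLowPass[[nm]]
    if (is.null(l))
      stop(sprintf("unsupported wavelet '%s'; valid wavelets: %s",
                   nm, paste(availableWavelets(), collapse = ", ")))
    lt <- l
  } else {
    tab <- .biorLowPass[[spec@order]]
    if (fam == "bior") { l <- tab$l; lt <- tab$lt }
    else               { l <- tab$lt; lt <- tab$l }   # rbio: dual roles swapped
  }
  n2 <- length(l)               # 2n + 2
  i <- seq_len(n2) - 1L         # 0-based filter index
  sgn <- (-1)^i
  h  <- sgn * lt[n2 - i]        # h_i  = (-1)^i lt_{2n+1-i}
  ht <- sgn * l[n2 - i]         # ht_i = (-1)^i l_{2n+1-i}
  new("WaveletFilterBank",
      analysisLow = l, analysisHigh = h,
      synthesisLow = lt, synthesisHigh = ht, spec = spec)
}

#' @describeIn filterAccessors analysis low-pass coefficients
#' @export
analysisLow <- function(bank) bank@analysisLow
#' @describeIn filterAccessors analysis high-pass coefficients
#' @export
analysisHigh <- function(bank) bank@analysisHigh
#' @describeIn filterAccessors synthesis low-pass coefficients
#' @export
synthesisLow <- function(bank) bank@synthesisLow
#' Filter bank accessors
#'
#' @param bank a [WaveletFilterBank-class].
#' @return numeric coefficient vector.
#' @name filterAccessors
#' @describeIn filterAccessors synthesis high-pass coefficients
#' @export
synthesisHigh <- function(bank) bank@synthesisHigh

#' Numerically validate a filter bank
#'
#' Computes the residuals of every filter-bank identity and returns them as
#' a named numeric vector; the caller decides pass/fail (the package's own
#' tests use 1e-8). Residuals:
#' \describe{
#'   \item{unitEnergy}{`|sum(l^2) - 1|` (meaningful for orthogonal banks).}
#'   \item{dcGain}{`|sum(l) - sqrt(2)|`.}
#'   \item{qmfCross}{`|sum(l * h)|`, low/high cross-orthogonality.}
#'   \item{qmfRecurrence}{max deviation of `h`, `ht` from the
#'     alternating-sign index-reversal of the dual low-pass filters.}
#'   \item{dualDelta}{max over shifts `m` of
#'     `|sum_k l_k lt_{k+2m} - delta(m)|`, the biorthogonal
#'     perfect-reconstruction identity (for orthogonal banks this is
#'     double-shift orthonormality).}
#'   \item{highPassZeroSum}{`|sum(h)|`, vanishing moment 0.}
#' }
#'
#' @param bank a [WaveletFilterBank-class].
#' @return named numeric vector of non-negative residuals.
#' @examples
#' validateBank(buildFilterBank("sym6"))
#' @export
validateBank <- function(bank) {
  stopifnot(is(bank, "WaveletFilterBank"))
  l <- bank@analysisLow; h <- bank@analysisHigh
  lt <- bank@synthesisLow; ht <- bank@synthesisHigh
  n2 <- length(l)
  i <- seq_len(n2) - 1L
  sgn <- (-1)^i
  qmfRec <- max(abs(h - sgn * lt[n2 - i]), abs(ht - sgn * l[n2 - i]))
  shifts <- seq(-(n2 %/% 2L) + 1L, n2 %/% 2L - 1L)
  dualDelta <- max(vapply(shifts, function(m) {
    k <- seq_len(n2)
    k2 <- k + 2L * m
    ok <- k2 >= 1L & k2 <= n2
    abs(sum(l[k[ok]] * lt[k2[ok]]) - as.numeric(m == 0L))
  }, numeric(1)))
  c(unitEnergy = abs(sum(l^2) - 1),
    dcGain = abs(sum(l) - sqrt(2)),
    qmfCross = abs(sum(l * h)),
    qmfRecurrence = qmfRec,
    dualDelta = dualDelta,
    highPassZeroSum = abs(sum(h)))
}

setMethod("show", "WaveletSpec", function(object) {
  cat(sprintf("WaveletSpec: %s (family %s, order %s)\n",
              waveletName(object), object@family, object@order))
})

setMethod("show", "WaveletFilterBank", function(object) {
  cat(sprintf("WaveletFilterBank '%s': length-%d filters\n",
              waveletName(object@spec), length(object@analysisLow)))
  cat("  analysis low :", signif(object@analysisLow, 4), "\n")
  cat("  analysis high:", signif(object@analysisHigh, 4), "\n")
  res <- validateBank(object)
  keep <- if (object@spec@family %in% c("haar", "db", "sym")) names(res)
          else c("dcGain", "qmfRecurrence", "dualDelta", "highPassZeroSum")
  cat(sprintf("  max identity residual: %.2e\n", max(res[keep])))
})
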