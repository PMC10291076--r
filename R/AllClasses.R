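#' @import methods
NULL

#' Electrode layout of an sEMG acquisition device
#'
#' Describes one or more rectangular electrode arrays and the mapping from
#' channel index to a grid position. The high-density (HD) device consists of
#' two 48-channel (6 x 8) arrays over the forearm extensor and flexor muscles
#' plus two 16-channel (4 x 4) arrays over the biceps and triceps, 128
#' channels in total; the low-density (LD) configuration is 8 discrete
#' channels.
#'
#' @slot arrays data.frame with one row per array: \code{array} (id),
#'   \code{rows}, \code{cols}, \code{spacing} (inter-electrode distance, mm).
#' @slot map data.frame with one row per channel: \code{channel},
#'   \code{array}, \code{row}, \code{col} (1-based grid coordinates).
#' @seealso [hdLayout()], [ldLayout()], [selectLdChannels()]
#' @export
setClass("ElectrodeLayout",
  representation(arrays = "data.frame", map = "data.frame"))

setValidity("ElectrodeLayout", function(object) {
  a <- object@arrays; m <- object@map
  if (!all(c("array", "rows", "cols", "spacing") %in% names(a)))
    return("arrays must have columns array, rows, cols, spacing")
  if (!all(c("channel", "array", "row", "col") %in% names(m)))
    return("map must have columns channel, array, row, col")
  if (anyDuplicated(m$channel)) return("duplicate channel ids")
  if (nrow(m) != sum(a$rows * a$cols))
    return("channel count does not match total array size")
  key <- paste(m$array, m$row, m$col)
  if (anyDuplicated(key)) return("two channels map to the same grid position")
  for (i in seq_len(nrow(a))) {
    mi <- m[m$array == a$array[i], ]
    if (any(mi$row < 1 | mi$row > a$rows[i] | mi$col < 1 | mi$col > a$cols[i]))
      return("channel position outside its array grid")
  }
  TRUE
})

#' A single multichannel sEMG recording
#'
#' One gesture repetition: a channels x samples signal matrix at a fixed
#' sampling rate together with its provenance labels (subject, trial,
#' gesture, repetition) and the electrode layout it was recorded with.
#'
#' @slot signal numeric matrix, channels x samples (arbitrary amplitude
#'   units).
#' @slot samplingRate sampling frequency in Hz.
#' @slot subject,trial,gesture,repetition integer labels.
#' @slot layout an [ElectrodeLayout-class].
#' @export
setClass("EmgRecording",
  representation(signal = "matrix", samplingRate = "numeric",
    subject = "integer", trial = "integer", gesture = "integer",
    repetition = "integer", layout = "ElectrodeLayout"))

setValidity("EmgRecording", function(object) {
  if (!is.numeric(object@signal)) return("signal must be numeric")
  if (!all(is.finite(object@signal))) return("signal must be finite")
  if (nrow(object@signal) != nrow(object@layout@map))
    return("signal rows must match layout channel count")
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    return("samplingRate must be a positive scalar")
  TRUE
})

#' A set of windowed gesture samples
#'
#' Container for the sample units the classifiers consume: real-valued
#' windows in [0, 1] (\code{kind = "real"}, the CNN/LSTM input and the spike
#' encoder's input), binary spike samples (\code{kind = "spike"}, the SNN
#' input), or time-domain feature vectors (\code{kind = "feature"}, the LDA
#' input, 4 columns MAV/VAR/WL/ZC).
#'
#' @slot data numeric array channels x width x n; width is the window length
#'   T for real/spike samples and 4 for feature samples.
#' @slot labels data.frame with n rows: subject, trial, gesture, repetition,
#'   window.
#' @slot kind one of "real", "spike", "feature".
#' @slot meta list of provenance (e.g. encoder mode and threshold).
#' @export
setClass("SampleSet",
  representation(data = "array", labels = "data.frame", kind = "character",
    meta = "list"),
  prototype(meta = list()))

setValidity("SampleSet", function(object) {
  d <- object@data
  if (length(dim(d)) != 3) return("data must be a 3-d array")
  if (dim(d)[3] != nrow(object@labels))
    return("third dimension of data must match label rows")
  if (!object@kind %in% c("real", "spike", "feature"))
    return("kind must be real, spike or feature")
  if (object@kind == "spike" && length(d) && !all(d %in% c(0, 1)))
    return("spike samples must be binary")
  if (!all(c("subject", "trial", "gesture", "repetition") %in%
           names(object@labels)))
    return("labels must have subject, trial, gesture, repetition")
  TRUE
})

#' Parameters of the leaky integrate-and-fire neuron
#'
#' The voltage-current variant ("lif-vi") evolves two coupled leaky states,
#' the synaptic current I (decay factor mu = exp(-1/tauSyn)) and the membrane
#' voltage U (decay factor tau = exp(-1/tauMem)); the plain variant ("lif-v")
#' drops the current dynamics (mu = 0). A neuron fires when U >= vThr2 and is
#' then reset to U * (1 - penalty); with penalty > 1 the post-spike voltage is
#' negative, which suppresses immediate re-firing.
#'
#' @slot tauMem membrane time constant (time steps), default 10.
#' @slot tauSyn synaptic-current time constant (time steps), default 5.
#' @slot vThr2 firing threshold, default 10.
#' @slot penalty reset penalty p, default 1.5.
#' @slot r membrane resistance, fixed at 1.
#' @slot variant "lif-vi" or "lif-v".
#' @export
setClass("LifParams",
  representation(tauMem = "numeric", tauSyn = "numeric", vThr2 = "numeric",
    penalty = "numeric", r = "numeric", variant = "character"))

setValidity("LifParams", function(object) {
  if (object@tauMem <= 0) return("tauMem must be positive")
  if (object@variant == "lif-vi" && object@tauSyn <= 0)
    return("tauSyn must be positive")
  if (!object@variant %in% c("lif-vi", "lif-v"))
    return("variant must be lif-vi or lif-v")
  TRUE
})

#' A two-hidden-layer spiking neural network
#'
#' Input spikes feed a first LIF hidden layer; its spikes feed a second LIF
#' layer with one neuron per gesture class. The readout is the softmax of the
#' second layer's membrane voltage averaged over the integration window.
#'
#' @slot W1 hidden x input weight matrix; @slot b1 hidden biases.
#' @slot W2 output x hidden weight matrix; @slot b2 output biases.
#' @slot params [LifParams-class] shared by both layers.
#' @slot timeSteps integration window T (equal to the encoding window).
#' @export
setClass("SnnNetwork",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix",
    b2 = "numeric", params = "LifParams", timeSteps = "integer"))

setValidity("SnnNetwork", function(object) {
  if (nrow(object@W1) != length(object@b1)) return("W1/b1 size mismatch")
  if (nrow(object@W2) != length(object@b2)) return("W2/b2 size mismatch")
  if (ncol(object@W2) != nrow(object@W1))
    return("W2 input size must equal W1 output size")
  if (object@timeSteps < 1) return("timeSteps must be >= 1")
  TRUE
})

#' Inference-power decomposition
#'
#' Named accumulate/multiply-accumulate cost terms (relative energy units,
#' AC = 0.1, MAC = 3.1) and their total.
#'
#' @slot components named numeric vector of per-term costs.
#' @slot total sum of components.
#' @export
setClass("PowerReport",
  representation(components = "numeric", total = "numeric"))

setValidity("PowerReport", function(object) {
  if (is.null(names(object@components))) return("components must be named")
  if (any(object@components < 0)) return("components must be non-negative")
  if (!isTRUE(all.equal(sum(object@components), object@total)))
    return("total must equal the sum of components")
  TRUE
})

#' Linear discriminant analysis model
#'
#' Per-class means, pooled within-class covariance with diagonal shrinkage,
#' and class priors; classification by the Gaussian discriminant with a
#' shared covariance.
#'
#' @slot means classes x features matrix of class means.
#' @slot covInv inverse of the regularised pooled covariance.
#' @slot priors class prior probabilities.
#' @slot classes class labels.
#' @export
setClass("LdaModel",
  representation(means = "matrix", covInv = "matrix", priors = "numeric",
    classes = "integer"))
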