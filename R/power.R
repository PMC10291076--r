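# Inference-power model based on operation counts: an accumulate (AC) costs
# 0.1 relative energy units, a multiply-accumulate (MAC) costs 3.1 (a 32-bit
# floating-point MAC consumes 31x the power of an AC on 45 nm CMOS). Spiking
# layers perform ACs gated by the spike release rate plus two MACs per
# neuron per step for the state updates; dense layers perform MACs
# throughout. The formulas are implemented verbatim, idealisations included
# (the CNN FC term uses H*W*C2 regardless of the realised flatten size; the
# LSTM FC term is multiplied by T): the model is an operation-count
# idealisation, not a profile of this implementation.

#' AC/MAC relative cost constants
#' @return list with `ac` = 0.1 and `mac` = 3.1.
#' @export
costConstants <- function() list(ac = 0.1, mac = 3.1)

powerReport <- function(components) {
  new("PowerReport", components = components, total = sum(components))
}

#' Power of adaptive spike encoding
#'
#' Per channel, the mean of the T differences costs T ACs + 1 MAC and the
#' standard deviation costs T ACs + (T + 1) MACs.
#'
#' @param T encoding time window. @param ch number of channels.
#' @return a [PowerReport-class] with components `mean` and `std`.
#' @export
encodingPower <- function(T, ch) {
  k <- costConstants()
  powerReport(c(mean = (T * k$ac + k$mac) * ch,
                std = (T * k$ac + (T + 1) * k$mac) * ch))
}

#' Power of the two SNN layers
#'
#' Layer 1: T * (SRR1 * i * h * 0.1 + 2 * h * 3.1); layer 2:
#' T * (SRR2 * o * h * 0.1 + 2 * o * 3.1). Spike-gated synaptic ACs plus two
#' state-update MACs per neuron per step.
#'
#' @param T integration window. @param i,h,o input, hidden and output layer
#'   sizes. @param srr1 spike release rate of the input samples.
#' @param srr2 spike release rate of the first hidden layer.
#' @return a [PowerReport-class] with components `layer1` and `layer2`.
#' @export
snnPower <- function(T, i, h, o, srr1, srr2) {
  stopifnot(srr1 >= 0, srr1 <= 1, srr2 >= 0, srr2 <= 1)
  k <- costConstants()
  powerReport(c(
    layer1 = T * (srr1 * i * h * k$ac + 2 * h * k$mac),
    layer2 = T * (srr2 * o * h * k$ac + 2 * o * k$mac)))
}

#' Total SNN inference power (encoding + network)
#'
#' @inheritParams snnPower
#' @param ch number of EMG channels (equal to the SNN input size).
#' @return a [PowerReport-class] with components `mean`, `std`, `layer1`,
#'   `layer2`.
#' @export
snnTotalPower <- function(T, ch, i, h, o, srr1, srr2) {
  stopifnot(ch == i)
  powerReport(c(powerComponents(encodingPower(T, ch)),
                powerComponents(snnPower(T, i, h, o, srr1, srr2))))
}

#' LSTM inference power
#'
#' LSTM layer: T * 4 * (i*h + h*h) * 3.1; FC layer: T * h * o * 3.1.
#'
#' @param T sequence length. @param i,h,o input, hidden and output sizes.
#' @return a [PowerReport-class] with components `lstm` and `fc`.
#' @export
lstmPower <- function(T, i, h, o) {
  k <- costConstants()
  powerReport(c(lstm = T * 4 * (i * h + h * h) * k$mac,
                fc = T * h * o * k$mac))
}

#' CNN inference power
#'
#' Convolutional blocks: k1*k2*H*W*(C*C1 + C1*C2) * 3.1; FC layer:
#' 3.1 * H * W * C2 * o.
#'
#' @param k1,k2 kernel size. @param H,W input spatial size.
#' @param C input channels. @param C1,C2 filters of the two blocks.
#' @param o output classes.
#' @return a [PowerReport-class] with components `conv` and `fc`.
#' @export
cnnPower <- function(k1, k2, H, W, C, C1, C2, o) {
  k <- costConstants()
  powerReport(c(conv = k1 * k2 * H * W * (C * C1 + C1 * C2) * k$mac,
                fc = k$mac * H * W * C2 * o))
}
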