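# Shared fixtures, built lazily and cached for the whole test run.

.fix <- new.env(parent = emptyenv())

memoFix <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

## the reference multi-shell gradient table: 26 b=0 + 32/64/128 directions
fullGtab <- function() memoFix("fullGtab", function()
  makeGradientTable(acquisitionSpec(), seed = 42L))

## noise-free default phantom (one straight bundle, low background f)
phantomNF <- function() memoFix("phantomNF", function()
  buildPhantom(phantomSpec(snr = Inf), fullGtab()))

## noise-free phantom with a free-water lesion in the bundle middle
phantomLesionNF <- function() memoFix("phantomLesionNF", function()
  buildPhantom(phantomSpec(
    lesions = list(list(min = c(6, 1, 1), max = c(9, 12, 7), f = 0.6)),
    snr = Inf), fullGtab()))

## single-voxel DWIVolume from a signal vector
voxelDwi <- function(signal, gtab) {
  n <- if (is.matrix(signal)) nrow(signal) else 1L
  sig <- if (is.matrix(signal)) signal else matrix(signal, 1)
  new("DWIVolume", signal = array(sig, c(n, 1, 1, ncol(sig))),
      affine = diag(4), gtab = gtab,
      brainMask = array(TRUE, c(n, 1, 1)), wmMask = array(TRUE, c(n, 1, 1)))
}

## standard prolate white-matter tensor (mm^2/s)
wmTensor <- function() diag(c(1.7, 0.2, 0.2) * 1e-3)

## single-tensor mixture signal shorthand
mixSignal <- function(f, gtab, s0 = 100, snr = Inf, seed = 1L,
                      tensor = wmTensor()) {
  simulateMixtureSignal(list(list(tensor = tensor, fraction = 1)),
                        f = f, s0 = s0, gtab = gtab, snr = snr, seed = seed)
}
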