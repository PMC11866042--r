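# Independent scalar CIELAB oracle (straight-line transcription of the
# standard sRGB -> XYZ(D65) -> L*a*b* formulas, kept separate from the
# package's vectorised implementation) plus the inverse, used only to
# check round-trips.

lab_oracle <- function(r, g, b) {
  lin <- function(u) {
    u <- u / 255
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  rl <- lin(r); gl <- lin(g); bl <- lin(b)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  fx <- lab_f(X / 0.95047); fy <- lab_f(Y / 1); fz <- lab_f(Z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

lab_f <- function(t) {
  if (t > 216 / 24389) t^(1 / 3) else (24389 / 27 * t + 16) / 116
}

lab_f_inv <- function(ft) {
  t3 <- ft^3
  if (t3 > 216 / 24389) t3 else (116 * ft - 16) * 27 / 24389
}

lab_to_rgb_oracle <- function(L, a, b) {
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  X <- lab_f_inv(fx) * 0.95047
  Y <- lab_f_inv(fy) * 1
  Z <- lab_f_inv(fz) * 1.08883
  rl <- 3.2404542 * X - 1.5371385 * Y - 0.4985314 * Z
  gl <- -0.9692660 * X + 1.8760108 * Y + 0.0415560 * Z
  bl <- 0.0556434 * X - 0.2040259 * Y + 1.0572252 * Z
  delin <- function(u) {
    if (u <= 0.0031308) 12.92 * u else 1.055 * u^(1 / 2.4) - 0.055
  }
  255 * c(delin(rl), delin(gl), delin(bl))
}
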