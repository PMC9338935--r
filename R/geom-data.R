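# Idealized nucleic-acid geometry in the base-pair reference frame.
# Base heavy atoms (+ C1') placed so that Watson-Crick partners are
# related by a 180-degree rotation about the frame x axis; shared
# B-form sugar-phosphate template with canonical B_I torsions, phosphate
# position calibrated so an ideal fiber duplex shows the 11.7 A
# minimal cross-strand P-P distance across the minor groove.

.base_geom <- list(
  A = {m <- rbind(
    c(-1.299889, 4.414375, 0.000000),
    c(0.000856, 4.817767, 0.000000),
    c(0.787593, 3.781321, 0.000000),
    c(0.043326, 2.649432, 0.000000),
    c(0.333729, 1.275128, 0.000000),
    c(1.643535, 0.828295, 0.000000),
    c(-0.678439, 0.413683, 0.000000),
    c(-1.930007, 0.830810, 0.000000),
    c(-2.250270, 2.107165, 0.000000),
    c(-1.305826, 3.042761, 0.000000),
    c(-2.478000, 5.286070, 0.000000))
    rownames(m) <- c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4", "C1'"); colnames(m) <- c("x","y","z"); m},
  C = {m <- rbind(
    c(-1.305741, 4.528987, 0.000000),
    c(-1.469839, 3.194637, 0.000000),
    c(-2.597473, 2.728595, 0.000000),
    c(-0.421363, 2.373004, 0.000000),
    c(0.814880, 2.852184, 0.000000),
    c(1.890441, 1.994384, 0.000000),
    c(1.020463, 4.246754, 0.000000),
    c(-0.054765, 5.068628, 0.000000),
    c(-2.478000, 5.407069, 0.000000))
    rownames(m) <- c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6", "C1'"); colnames(m) <- c("x","y","z"); m},
  G = {m <- rbind(
    c(-1.307615, 4.527658, 0.000000),
    c(-0.002216, 4.922958, 0.000000),
    c(0.775454, 3.879200, 0.000000),
    c(0.017496, 2.755580, 0.000000),
    c(0.307901, 1.371173, 0.000000),
    c(1.460670, 0.975296, 0.000000),
    c(-0.724072, 0.499755, 0.000000),
    c(-2.008396, 0.953230, 0.000000),
    c(-3.036069, 0.044542, 0.000000),
    c(-2.291269, 2.236531, 0.000000),
    c(-1.322903, 3.159601, 0.000000),
    c(-2.478000, 5.407069, 0.000000))
    rownames(m) <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4", "C1'"); colnames(m) <- c("x","y","z"); m},
  T = {m <- rbind(
    c(-1.326418, 4.431381, 0.000000),
    c(-1.457800, 3.026200, 0.000000),
    c(-2.541092, 2.438553, 0.000000),
    c(-0.251339, 2.318549, 0.000000),
    c(1.028645, 2.852008, 0.000000),
    c(2.049305, 2.169474, 0.000000),
    c(1.086140, 4.338096, 0.000000),
    c(2.431374, 4.990236, 0.000000),
    c(-0.067605, 5.018618, 0.000000),
    c(-2.478000, 5.286070, 0.000000))
    rownames(m) <- c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6", "C1'"); colnames(m) <- c("x","y","z"); m}
)

.backbone_geom <- {m <- rbind(
    c(0.169786, 9.459540, -1.784186),
    c(-0.637704, 10.632577, -2.205101),
    c(1.429292, 9.688041, -1.031419),
    c(-0.741271, 8.423120, -1.013776),
    c(-1.910294, 8.228581, -1.800280),
    c(-2.924492, 7.279804, -1.240405),
    c(-2.481735, 5.902203, -1.301450),
    c(-3.238780, 7.511815, 0.222528),
    c(-4.644233, 7.385125, 0.259404),
    c(-2.446480, 6.475342, 0.999011))
  rownames(m) <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'"); colnames(m) <- c("x","y","z"); m}
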