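# Fixed design constants of the synthetic-data module.
#
# Proteins and compounds carry a hidden 3-dimensional latent vector. The
# latent tilts the observable content (amino-acid composition; atom, halogen
# and ring frequencies) so that sum-embeddings of the observable tokens are a
# noisy linear image of the latent. Interaction and sensitivity labels are
# functions of the latents only, so recovering them from sequence/SMILES is a
# genuine learning task rather than a lookup.

LATENT_DIM <- 2L

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CHAIN_ATOMS <- c("C", "N", "O", "S")
HALOGENS <- c("F", "Cl", "Br", "I")

# Tilt maps, fixed once for the lifetime of the package so that every
# generator call (any seed) lives in the same latent geometry.
TILT_AA <- with_seed(990001L, matrix(rnorm(20L * LATENT_DIM), 20L, LATENT_DIM,
                                     dimnames = list(AA_ALPHABET, NULL)))
TILT_ATOM <- with_seed(990002L, matrix(rnorm(4L * LATENT_DIM, sd = 1.2), 4L,
                                       LATENT_DIM,
                                       dimnames = list(CHAIN_ATOMS, NULL)))
TILT_HALOGEN <- c(1.2, -0.8)
TILT_RING <- c(-0.7, 1.1)
TILT_DOUBLE <- c(0.4, -0.9)
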