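# Regenerates the deterministic synthetic fixtures under inst/extdata/.
# Run from the repo root:  Rscript scripts/make_fixtures.R
# (then refresh inst/extdata/CHECKSUMS with md5sum)
set.seed(20260921)

lam <- c(A=0.730, R=0.000, N=0.432, D=0.378, C=0.595, Q=0.514, E=0.459,
         G=0.649, H=0.514, I=0.973, L=0.973, K=0.514, M=0.838, F=1.000,
         P=1.000, S=0.595, T=0.676, W=0.946, Y=0.865, V=0.892)

## Synthetic MJ-like contact matrix: e_ij = 1.0 - 2.5*(lambda_i + lambda_j).
## Symmetric by construction; hydrophobic pairs attractive under the
## KH model-D mapping (e < e0 = -1.8), charged/polar pairs repulsive.
aa <- names(lam)
M <- outer(lam, lam, function(a, b) round(1.0 - 2.5 * (a + b), 4))
con <- file("inst/extdata/mj_matrix_synthetic.tsv", "w")
writeLines(c(
  "# SYNTHETIC stand-in for the Miyazawa-Jernigan residue-residue contact",
  "# energy matrix (units kcal/mol as consumed by the KH model-D mapping).",
  "# Constructed as e_ij = 1.0 - 2.5*(lambda_i + lambda_j) from the HPS",
  "# hydropathy scale; NOT the published statistical potential.",
  paste(c("code", aa), collapse = "\t")), con)
for (a in aa)
  writeLines(paste(c(a, formatC(M[a, ], format = "f", digits = 4)),
                   collapse = "\t"), con)
close(con)

## Synthetic Cdc15-IDR-like sequence, residues 327-854 (528 aa), with S/T
## pinned at the 31 fixture phosphosites.  Weak-polyampholyte composition.
sites <- read.table("inst/extdata/cdc15_phosphosites_synthetic.tsv",
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
n <- 528; off <- 327
pool <- c(S=0.12, T=0.08, G=0.10, N=0.08, Q=0.07, P=0.08, A=0.09,
          K=0.07, R=0.04, D=0.06, E=0.06, L=0.04, I=0.02, V=0.04,
          F=0.02, M=0.01, H=0.01, Y=0.01)
seqv <- sample(names(pool), n, replace = TRUE, prob = pool)
idx <- sites$site - off + 1
stopifnot(all(idx >= 1 & idx <= n))
seqv[idx] <- sites$residue
lines <- c(">cdc15_idr_synthetic 327-854 synthetic stand-in sequence",
           vapply(split(seqv, ceiling(seq_len(n) / 60)), paste0,
                  character(1), collapse = ""))
writeLines(lines, "inst/extdata/cdc15_idr_synthetic.fasta")
cat("wrote fixtures\n")
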