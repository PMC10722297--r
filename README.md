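# allohex

Detection of homoeologous exchanges and LTR insertion-time dating for
segmental allotetraploid genomes, with a fully ground-truthed synthetic
test universe.

## The problem

Sour cherry (*Prunus cerasus*, 2n = 4x = 32) is a segmental allotetraploid:
one subgenome derives from sweet cherry (*P. avium*, "subgenome a") and one
from ground cherry (*P. fruticosa*, "subgenome f").  After hybridisation,
chromosomal segments are occasionally replaced by the corresponding
(homoeologous) segment of the other subgenome through duplication–deletion
events, leaving a mosaic of truly allopolyploid and autopolyploid-like
regions.  Finding those homoeologous exchanges (HE) — and dating how long
the two ancestral gene pools have been separated — is the core of this
package.

## The method

Three independent windowed evidence tracks are computed on the hybrid
genome and intersected:

1. **Genomic coverage (100-kb windows).**  Hybrid whole-genome read pairs
   are mapped to both ancestral genomes, filtered to properly paired
   primary alignments (`-f 3 -F 2304`), and partitioned into four classes:
   unique to ancestor A, unique to ancestor F, both, neither.  The two
   unique sets are re-mapped onto the hybrid; a subgenome-a window is
   flagged when the fraction of bases covered by A-unique reads
   (intraspecific) is *less* than the fraction covered by F-unique reads
   (interspecific), and mirror-wise for subgenome f.
2. **RNA coverage (250-kb windows).**  Per-window fractions of covered
   bases from the hybrid's RNA-seq and from each ancestral species' RNA-seq
   are differenced: for a subgenome-a window the intraspecific difference
   (hybrid − *P. avium*) should sit near zero, below the interspecific one
   (hybrid − *P. fruticosa*); the opposite ordering raises the flag.
3. **Protein identity (250-kb windows).**  Each predicted protein carries
   its percent amino-acid identity (IAA) to the best homolog in either
   ancestral annotation; a window is flagged when proteins more similar to
   the homoeologous ancestor outnumber those more similar to the own
   ancestor.  A 70% quantile comparison of the identities in 1-Mb windows
   (linear interpolation between order statistics) annotates confirmed
   regions.

Windows flagged by **all three** tracks are merged (maximal runs of
adjacent 250-kb windows) into directed HE regions.

Independently, LTR retrotransposons are dated with the molecular clock

    T = K / (2 µ),   K = 1 − identity(left LTR, right LTR)

at the *Prunus*-specific rate µ = 7.7 × 10⁻⁹ substitutions · site⁻¹ ·
generation⁻¹, and elements shared between (sub)genomes are identified as
same-family, same-insertion-time elements in the same positional order
(a maximum collinear matching).  Because generation times of wild cherries
are uncertain, ages in years are reported as a sweep over 10–60
years/generation.

Everything is exercised end to end on a built-in seeded simulator: two
ancestors diverged by 3%, a hybrid with 0.2% drift and planted
duplication–deletion HE segments, error-free 150-bp read pairs (~550-bp
inserts, 20×), anchored proteins with computed identities, origin-aware
RNA coverage tracks, and LTR pass-lists — each with machine-readable truth.

## Worked example

```r
library(allohex)

res <- run_pipeline(sim_config(seed = 1))
print(res)
```

```
Synthetic allotetraploid HE pipeline run
  genome: 2 chromosomes/subgenome x 5.0 Mb, divergence 0.030, drift 0.0020
  fragments: UNIQUE_A 357092 | UNIQUE_F 371599 | BOTH 72 | NEITHER 604570
Homoeologous exchange calls
  qualifying 250-kb windows: 27 (a: 14, f: 13)
  merged regions: 6 (a: 3, f: 3)
  total exchanged sequence: 6.75 Mb
  vs planted truth: recall 1.000, precision 1.000 (n_truth 6)
```

The fragment classes show the expected structure: at 0.2% drift only ~55%
of error-free pairs match their own ancestor exactly (both mates must be
substitution-free), ~0.005% match both, and the six planted exchanges of
0.5–2 Mb are recovered exactly, each call being a run of 250-kb windows
flagged by all three evidence tracks.  The LTR side of the same run dates
the youngest element shared between subgenome a and *P. avium* at

```r
res$ltr_youngest[["a_vs_avium"]]
#> [1] 103896.1
```

i.e. about 103,900 generations, or ~1.0–6.2 Mya across the 10–60
years/generation sweep.

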