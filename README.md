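# phagecell

Single-cell quantification of mycobacteriophage adsorption and infection
from multi-channel fluorescence microscopy, with a fully seeded synthetic
microscopy generator for validation.

## The problem

Mycobacteriophages — viruses of *Mycobacterium* with real therapeutic
potential — adsorb to the bacterial surface as the first step of
infection. Live-cell imaging with a fluorogenic probe for newly
synthesised cell wall (green) and dye-stained phage particles (red puncta)
suggests that phages preferentially attach at sites of new wall synthesis:
the growing poles and division septa. Testing that claim, and following
what happens after DNA injection, requires per-cell image quantification:

* **Spline colocalization** (the core statistic). Lines are drawn
  perpendicular to each segmented cell's surface. A line is **phage
  proximal** when its red-channel peak height `h` satisfies
  `h > μ_bg + k·σ_bg` (strict; `k = 1`), where `μ_bg`, `σ_bg` are the mean
  and SD of the cell-free image background. The background-subtracted
  maximum of the intramembrane green signal is then summarised (median,
  quartiles) for proximal vs non-proximal lines.
* **Circumference-normalized adsorption.** Per cell,
  `A = Σ_peaks max(h_i − μ_bg, 0) / C` with `C` the boundary length;
  two conditions are compared with a pooled two-sample Student's t-test.
* **Reporter time-lapses.** Cells tracked by mask overlap (IoU), mCherry
  traces extracted and background-subtracted, expression onset detected
  (threshold + persistence), and each track classified as
  expressed-and-lysed, outgrowth, or uninfected.
* **Genome GC landscape.** Sliding-window GC% of phage genomes
  (`(G+C)/(A+C+G+T)`, ambiguity codes excluded) and calls of locally
  GC-depressed regions — candidate loci for the AT-preferring
  nucleoid-associated protein Lsr2.

Raw imaging data for this system are not publicly deposited, so the
package ships `simulate_scene()` / `simulate_timelapse()`: seeded
generators of rod-shaped cells with polar/septal green labelling,
surface-anchored phage puncta with tunable polar bias, reporter
expression with lysis/outgrowth fates, a Gaussian PSF and Poisson +
Gaussian camera noise — all with exact ground truth, so every pipeline
stage is validated by parameter recovery.

Intended users: microbiologists and image analysts quantifying
phage–host interactions in rod-shaped bacteria, and anyone needing a
ground-truthed synthetic benchmark for bacterial-cell image pipelines.

## Worked example

```r
library(phagecell)

cfg <- scene_config(n_cells = 12, seed = 42, image_shape = c(420, 420),
                    polar_bias = 0.9, polar_green_ratio = 3,
                    lateral_green_level = 0.1)
sc  <- simulate_scene(cfg)
sc
#> <phage_scene>
#>   channels: phase, green, red (420 x 420)
#>   12 cells, 31 phage particles, seed 42

mask <- segment_phase(sc$channels$phase, min_area = 80)
cc   <- run_coloc(sc$channels$green, sc$channels$red, mask)
glance(cc)
#>   n_cells n_lines n_proximal median_proximal median_non_proximal median_difference
#> 1      12     470        207           12.82               10.29             2.528
```

With 90% of particles targeted to poles/septa and a three-fold polar
green enrichment, lines proximal to a phage punctum carry a higher
background-subtracted green maximum (median 12.8 vs 10.3 intensity
units) — the colocalization signature the statistic is designed to
detect. `autoplot(cc)` draws the violin summary; `coloc_summary(cc)`
returns the medians and quartiles as a tibble.

Adsorption comparison between two (here identical) simulated strains:

```r
ad <- adsorption_table(sc$channels$red, mask)
students_t(ad$normalized_value[1:6], ad$normalized_value[7:12])
#>   group1 group2 n1 n2 mean1 mean2      t df p_value significant         method
#> 1      A      B  6  6 2.805 2.667 0.4678 10  0.6499       FALSE student_pooled
```

GC landscape of a synthetic 40-kb genome at 67.4% GC with two planted
50%-GC segments:

```r
genome <- simulate_genome(40000, gc = 0.674,
                          regions = tibble::tibble(start = c(10000, 28000),
                                                   end   = c(12000, 30000),
                                                   gc    = 0.5),
                          seed = 1)
track <- gc_sliding(genome)          # 500-bp windows, 100-bp steps
low_gc_regions(track)
#> # A tibble: 2 × 4
#>   start   end mean_gc depth_pp
#>   <dbl> <dbl>   <dbl>    <dbl>
#> 1  9900 12200   0.512     14.5
#> 2 27800 30200   0.509     14.8
```

Both planted dips are recovered (and nothing else); `gc_fraction()` on a
genome FASTA read with `read_fasta()` gives the overall GC%.

The methods vignette
(`vignettes/quantifying-phage-infection.Rmd`) documents the model behind
the generator, every tunable threshold, and the package's design
decisions.

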