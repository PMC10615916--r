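# smdistance

Grounded semantic similarity for researchers in cognitive psychology,
psycholinguistics and cognitive neuroscience. Where traditional similarity
measures come from taxonomies (WordNet path distance), feature-production
norms (feature overlap) or corpus statistics (CBOW embeddings),
**sensorimotor distance** is computed directly from how strongly people
experience a concept through each of 11 dimensions of perception and
action: six perceptual modalities (auditory, gustatory, haptic,
interoceptive, olfactory, visual) and five action effectors (foot/leg,
hand/arm, head, mouth/throat, torso), each rated on a 0–5 scale. Each
concept is an 11-dimensional vector of mean ratings; dissimilarity between
concepts *u* and *v* is the cosine distance

```
d(u, v) = 1 − (u · v) / (‖u‖ ‖v‖)
```

which lies in [0, 1] for non-negative ratings, with correlation, Euclidean,
Minkowski-3 and Mahalanobis distances available as alternatives (the last
whitens the dimensions' intercorrelational structure via a pseudo-inverted
covariance estimated from the whole table). At the scale of the published
39,707-concept sensorimotor norms this defines 788,303,071 unique concept
pairs, which the package summarises in a single streaming pass.

The package provides:

* validated loading of norms tables (CSV/TSV, user-overridable column map,
  case-insensitive word keys shared with the benchmark loaders);
* the five pairwise distance measures and covariance estimation;
* streaming whole-pair-space summaries (mean/SD, top-k extreme pairs,
  histogram) that never materialise the pair matrix, plus exact
  nearest-neighbour search;
* Sammon-mapping 2-D layouts with deterministic seeding and a
  non-increasing stress trace, and polar-profile export;
* benchmark evaluation against human similarity judgements (SimLex-999,
  WordSim-353, MEN and generic dialects): coverage, zero-order
  correlations, hierarchical ΔR² for the unique variance of sensorimotor
  distance, exhaustive best-subset ranking, and abstract/concrete splits
  at the concreteness midpoint;
* synthetic norms and benchmark generators with known ground truth;
* a command-line interface (`exec/smdistance`) with subcommands
  `distance`, `neighbours`, `summary`, `mds`, `bench`, `fixture`.

## Worked example

```r
library(smdistance)

# a synthetic 500-concept norms table with realistic correlation structure
norms <- generate_norms_fixture(500, seed = 2024)
norms
#> <norms_table> 500 concepts x 11 sensorimotor dimensions
#>   source: synthetic(seed=2024)

# stream all 124,750 unordered pairs
s <- summarize_distances(norms)
s
#> <distance_summary> metric=cosine  concepts=500  pairs=124750
#>   mean = 0.1028   sd = 0.0610
#>   closest pair:  w00114-w00228  0.003159
#>   furthest pair: w00101-w00199  0.7814

nearest_neighbours(norms, "w00042", k = 3)
#> <neighbour_result> query='w00042'  k=3
#>     word   distance
#> 1 w00412 0.01518513
#> 2 w00406 0.01660887
#> 3 w00045 0.01856259

# a benchmark whose scores are cosine similarity plus rating noise:
# human scores correlate negatively with distance, attenuated by the noise
bench <- generate_benchmark_fixture(norms, n_pairs = 1000,
                                    noise_sd = 0.05, seed = 7)
bench <- attach_distance(bench, norms)
correlate(bench)
#> $r
#> [1] -0.7600312
#> $n
#> [1] 1000

# 2-D Sammon layout of selected concepts
sammon_layout(norms, sprintf("w%05d", 1:8), seed = 11)
#> <sammon_layout> 8 points  metric=cosine  stress=0.0112  iterations=41
```

The summary's mean/SD describe the pair-distance distribution (self-pairs
excluded); the closest/furthest pairs are the retained extremes; the
neighbour listing is ascending exact cosine distance; the benchmark `r` is
the Pearson correlation between human score and sensorimotor distance over
the covered pairs (negative, since shorter distance means more similar);
the layout's stress is the Sammon criterion at convergence.

Equivalent CLI calls:

```sh
smdistance fixture --kind norms --n 500 --seed 2024 --out norms.csv
smdistance summary --norms norms.csv --out summary.json
smdistance neighbours --norms norms.csv --word w00042 --k 3
```

## Working with the published data

The package does not redistribute the Lancaster Sensorimotor Norms or the
benchmark datasets. To run the full published-scale checks, place the
files under `tests/testthat/published/`:

| file | contents |
|---|---|
| `lancaster_sensorimotor_norms.csv` | item-level norms, 39,707 rows, `Word` + `*.mean` columns |
| `SimLex-999.txt` | tab-separated, `word1`, `word2`, `SimLex999` columns |
| `wordsim_combined.csv` | `Word 1`, `Word 2`, `Human (mean)` columns |
| `MEN_dataset_natural_form_full` | space-separated `word1 word2 score` |
| `concreteness.csv` | `word`, `rating` columns on the 1–5 scale |

The two acceptance tests that reproduce the published pair-space
distribution (minimum ≈ .0002 for *cyan–pixilation*, maximum ≈ .950 for
*shinbone–smelled*, mean ≈ .195, SD ≈ .123) and the published coverage
figures (3,730 of 4,325 compiled pairs; Simlex 993/999; 264/172/557
abstract/mixed/concrete pairs) run against these files and fail when the
files are absent.

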