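# symdyn

Clustering and network analysis of depression symptom *dynamics* from
routine outcome monitoring, based on dynamic time warping (DTW).

## What problem this solves, and for whom

Clinicians and researchers who assess depressed patients repeatedly with
the 17-item Hamilton Rating Scale for Depression (HRSD-17) usually
collapse each visit into a sum score, discarding which symptoms change
together within a patient. `symdyn` keeps the item level: each of the 17
items traces an ordinal time series over biweekly visits, and the
similarity of two items' *time courses* is measured with DTW, an elastic
alignment that tolerates one symptom lagging another by up to two visits
(a Sakoe-Chiba band of 2). From the resulting distance matrices the
package builds, per patient and for a whole cohort:

* **Idiographic reports** — a patient's 136 pairwise item distances,
  a Ward.D2 cluster tree, and a symptom network with strength and
  closeness centrality (`analyze_patient()`);
* **Nomothetic results** — the assessment-weighted mean distance matrix,
  a scree/elbow choice of the cluster count, a Distatis
  (three-way MDS) compromise corroborating the clusters, per-item mixed
  trajectory models, and a comparison of network *density* (inverse mean
  DTW distance) between treatment responders/remitters and other
  patients (`analyze_cohort()`, `density_comparison()`);
* **A calibrated synthetic cohort generator** (`simulate_cohort()`) with
  planted five-cluster structure and response-linked synchrony, standing
  in for non-public clinical data in every test.

## The statistic at the core

For equal-length series $x, y$ (one HRSD item each, same visits), the DTW
distance is the minimal accumulated cost over monotone anchored alignment
paths under the symmetric $P=0$ step pattern,

$$g(i,j) = \min\bigl(g(i{-}1,j{-}1) + 2|x_i-y_j|,\; g(i{-}1,j) + |x_i-y_j|,\; g(i,j{-}1) + |x_i-y_j|\bigr),$$

with $g(1,1) = 2|x_1-y_1|$ and the band $|i-j| \le 2$. Short distances
mean synchronous symptom trajectories; a patient's mean pairwise distance
is their network density.

## Worked example

```r
library(symdyn)

cohort <- simulate_cohort(n_patients = 255, seed = 2)
rep <- analyze_cohort(cohort)
rep
#> Nomothetic DTW report (255 patients)
#>   clusters: k = 5 (elbow)
#>     1: items 3, 8, 9, 11, 12, 15, 16, 17
#>     2: items 4, 5, 6
#>     3: items 2, 10
#>     4: items 1, 7
#>     5: items 13, 14
#>   density vs outcome:
#> # A tibble: 2 × 7
#>   contrast  statistic  p.value n_yes  n_no median_yes median_no
#>   <chr>         <dbl>    <dbl> <int> <int>      <dbl>     <dbl>
#> 1 responder      2264 1.68e-18   173    82     -0.496     0.672
#> 2 remitter       2659 8.06e-20   145   110     -0.580     0.470
```

The elbow rule lands on five clusters, and the five groups are the
generator's planted structure: core symptoms (1 depressed mood, 7 work
and interests), the three insomnia items (4–6), distress (2 guilt, 10
psychic anxiety), somatic (13 general somatic, 14 genital), and the
eight-item inner-turmoil group. The density rows show that responders
and remitters have *smaller* adjusted mean DTW distances (negative
medians) than their complements — denser, more synchronous symptom
networks — with rank-sum p-values far below 0.05.

Per patient:

```r
analyze_patient(cohort, patient = "P001")   # distances, k = 3 cut, network
autoplot(patient_distance_matrix(cohort, "P001"))  # clustered heatmap
```

Everything returns tibbles (or has `tidy()`/`glance()` methods), so
results pipe straight into dplyr/ggplot2.

## Package layout

| File | Contents |
| --- | --- |
| `R/dtw.R`, `src/dtw.cpp` | banded DTW dynamic program + enumeration oracle |
| `R/distance.R` | per-patient and cohort distance matrices |
| `R/cluster.R`, `R/network.R` | Ward.D2 trees, scree/elbow, symptom networks |
| `R/distatis.R` | Distatis compromise, congruence coefficient |
| `R/outcomes.R` | response/remission, density comparison, trajectory models |
| `R/simulate.R` | the synthetic cohort generator |
| `R/io.R`, `R/pipeline.R`, `R/plots.R` | CSV I/O, report assembly, autoplot methods |

See `vignettes/symptom-dynamics.Rmd` for the methods account: model
conventions, generator design and calibration, numerical edge cases, and
known limitations.
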