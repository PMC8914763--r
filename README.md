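# irtasym

Automated thermal-asymmetry analysis of facial infrared thermograms for
screening of orofacial/maxillofacial abnormality.

A healthy face is thermally near-symmetric; focal pathology such as a
tumor perturbs local perfusion and shows up as a unilateral warm zone.
`irtasym` automates that reading for radiologists and medical-imaging
researchers working with thermal cameras: given a per-pixel temperature
matrix of the face and of the open mouth cavity (°C, delimited text), it

1. detects edges with the 3×3 **Prewitt gradient** and a relative
   magnitude threshold;
2. estimates the **symmetry axis** as the major axis of the direct
   least-squares ellipse fitted to the convex hull of the edge points;
3. splits the field into the two sides of the axis and extracts eight
   asymmetry features per patient — for each view *v* ∈ {f (face),
   m (mouth)}: ΔT_v = |mean_R − mean_L|, ΔT_vmax = |max_R − max_L|,
   ΔDEV_v = |MAD_R − MAD_L|, and n_v = #{warmer-side pixels exceeding
   the cooler side's maximum by more than 0.4 °C};
4. classifies patients into non-tumor (NT = 0) vs tumor (T = 1) classes
   with a **1-nearest-neighbor** classifier (Euclidean distance on the
   standardized feature vector), evaluated by 12 random 12-per-class
   training splits, a pooled confusion matrix, sensitivity/specificity/
   accuracy, and ROC/AUC from the signed nearest-neighbor margin.

Because clinical thermograms cannot be redistributed, the package ships
a phantom generator (`make_cohort()`) producing face/mouth thermogram
pairs with known symmetry axis, lesion ground truth and class labels
under realistic acquisition conditions (240×320 px, 22 °C background,
±0.06 °C sensor noise).

## Worked example

```r
library(irtasym)

coh <- make_cohort(23, 23, lesion_amp_c = 1.0, seed = 2026)  # 23 NT + 23 T
cf  <- cohort_features(coh, seed = 2027)   # edge -> axis -> split -> features
ds  <- labeled_dataset(cf$vectors, cf$labels)
evaluate_knn(ds, seed = 2028)
#> <classification_report>
#>   pooled over 12 repeats, 264 test decisions
#>   confusion: TP 132  FN 0  FP 0  TN 132
#>   sensitivity 1.000  specificity 1.000  accuracy 1.000
#>   AUC 1.0000
```

On this synthetic cohort (1.0 °C lesions, 8 px radius) the classifier
separates the classes perfectly: all 264 pooled test decisions over the
12 repetitions are correct. One tumor member's averaged feature vector
shows why:

```r
round(as.numeric(cf$vectors[[30]]), 3)
#> [1]  0.059  0.641 16.000  0.062  0.108  0.697 33.200  0.058
```

in `feature_names` order (dTf, dTfmax, nf, dDEVf, dTm, dTmmax, nm,
dDEVm): the lesion barely moves the side *means* (0.06–0.11 °C, below
the 0.4 °C abnormality threshold, so the transparent `is_asymmetric()`
screen alone misses it) but produces large max-temperature differences
(~0.6–0.7 °C) and dozens of exceedance pixels — exactly the features
the classifier exploits. A per-feature Welch t-test confirms the group
separation, e.g. for ΔT_mmax:

```r
feature_ttest(ds$features[1:23, "dTmmax"], ds$features[24:46, "dTmmax"])
#> t = 52.39, p = 1.1e-27
```

A command-line front end with `phantom`, `edges`, `axis`, `features`,
`classify` and `run` subcommands is installed at
`system.file("cli", "irtasym", package = "irtasym")`.

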