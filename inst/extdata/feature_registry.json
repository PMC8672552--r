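{
  "name": ["hist_mean", "hist_variance", "hist_skewness", "hist_kurtosis", "hist_median", "hist_minimum", "hist_maximum", "hist_p10", "hist_p90", "hist_entropy", "hist_uniformity", "glcm_joint_maximum", "glcm_joint_average", "glcm_joint_variance", "glcm_joint_entropy", "glcm_difference_average", "glcm_difference_variance", "glcm_difference_entropy", "glcm_sum_average", "glcm_sum_variance", "glcm_sum_entropy", "glcm_angular_second_moment", "glcm_contrast", "glcm_dissimilarity", "glcm_inverse_difference", "glcm_inverse_difference_normalized", "glcm_inverse_difference_moment", "glcm_inverse_difference_moment_normalized", "glcm_inverse_variance", "glcm_correlation", "glcm_autocorrelation", "glcm_cluster_tendency", "glcm_cluster_shade", "glcm_cluster_prominence", "glcm_information_correlation_1", "glcm_information_correlation_2", "glrlm_short_run_emphasis", "glrlm_long_run_emphasis", "glrlm_low_grey_level_run_emphasis", "glrlm_high_grey_level_run_emphasis", "glrlm_short_run_low_grey_level_emphasis", "glrlm_short_run_high_grey_level_emphasis", "glrlm_long_run_low_grey_level_emphasis", "glrlm_long_run_high_grey_level_emphasis", "glrlm_grey_level_non_uniformity", "glrlm_grey_level_non_uniformity_normalized", "glrlm_run_length_non_uniformity", "glrlm_run_length_non_uniformity_normalized", "glrlm_run_percentage", "glrlm_grey_level_variance", "glrlm_run_length_variance", "glrlm_run_entropy", "glszm_small_zone_emphasis", "glszm_large_zone_emphasis", "glszm_low_grey_level_zone_emphasis", "glszm_high_grey_level_zone_emphasis", "glszm_small_zone_low_grey_level_emphasis", "glszm_small_zone_high_grey_level_emphasis", "glszm_large_zone_low_grey_level_emphasis", "glszm_large_zone_high_grey_level_emphasis", "glszm_grey_level_non_uniformity", "glszm_grey_level_non_uniformity_normalized", "glszm_zone_size_non_uniformity", "glszm_zone_size_non_uniformity_normalized", "glszm_zone_percentage", "glszm_grey_level_variance", "glszm_zone_size_variance", "glszm_zone_entropy", "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness", "ngtdm_complexity", "ngtdm_strength"],
  "family": ["histogram", "histogram", "histogram", "histogram", "histogram", "histogram", "histogram", "histogram", "histogram", "histogram", "histogram", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLCM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLRLM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "GLSZM", "NGTDM", "NGTDM", "NGTDM", "NGTDM", "NGTDM"]
}
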