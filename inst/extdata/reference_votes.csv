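feature,display,chi2,fisher,info_gain,anova,rfe,perm_imp,boruta
total_intra_mst_total,total intra-cluster total MST distance,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
total_intra_n2n_max,total intra-cluster nucleus to nucleus maximum distance,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
inter_c2c_total,inter-cluster centroid to centroid total distance,TRUE,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
inter_mst_total,inter-cluster total MST distance,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
n_clusters,number of clusters,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
total_intra_mst_max,total intra-cluster maximum MST distance,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
avg_intra_n2n_min,average intra-cluster nucleus to nucleus minimum distance,FALSE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
avg_intra_n2n_max,average intra-cluster nucleus to nucleus maximum distance,FALSE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
avg_intra_mst_max,average intra-cluster maximum MST distance,FALSE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
avg_cluster_area,average cluster area,TRUE,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE
total_intra_n2n_total,total intra-cluster nucleus to nucleus total distance,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,TRUE
total_intra_mst_min,total intra-cluster minimum MST distance,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,TRUE
total_intra_n2n_min,total intra-cluster nucleus to nucleus minimum distance,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,TRUE
inter_mst_max,inter-cluster maximum MST distance,TRUE,TRUE,FALSE,FALSE,TRUE,FALSE,TRUE
avg_intra_mst_total,average intra-cluster total MST distance,FALSE,TRUE,TRUE,FALSE,TRUE,FALSE,TRUE
avg_intra_mst_min,average intra-cluster minimum MST distance,FALSE,TRUE,TRUE,TRUE,FALSE,FALSE,TRUE
total_cluster_area,total cluster area,TRUE,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE
inter_mst_avg,inter-cluster average MST distance,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,TRUE
avg_intra_n2n_avg,average intra-cluster nucleus to nucleus average distance,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,TRUE
inter_c2c_avg,inter-cluster centroid to centroid average distance,FALSE,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE
min_cluster_area,minimum area of a cluster,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE
avg_intra_n2n_total,average intra-cluster nucleus to nucleus total distance,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
inter_c2c_min,inter-cluster centroid to centroid minimum distance,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
inter_c2c_max,inter-cluster centroid to centroid maximum distance,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
max_cluster_area,maximum area of a cluster,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
inter_mst_min,inter-cluster minimum MST distance,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
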