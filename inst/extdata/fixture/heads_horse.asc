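ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
0.120809 0.0845036 0.0720227 0.511015 0.00914194 1.62715 0.282473 0.0149959 0.102729 0.161336 0.13191 0.997194 0.0951049 0.487979 3.31872 0.585877
0.0101565 0.531598 0.110656 0.260249 0.303646 0.0890889 0.113501 0.0228018 0.22047 0.0118935 0.169598 0.144537 0.559297  8.8219 1.99874 0.57988
0.114147 0.00956793 0.147651 0.0879992 0.682496 0.707665 0.0392006 0.364678 0.196593 0.165324 2.87866 2.87892 0.158532 0.385532 0.33757 0.0309947
0.335023 0.138432 1.91841 0.58256 0.0454995 0.0757078 0.246983 0.219061 1.05482 0.215909 0.799014 13.4058 0.867224 2.12533 0.743776 3.62064
0.680805  0.1026 0.0514887 0.643052 0.437188  0.5808 0.339584 0.385765 0.426585 2.23147 0.714076 0.804385 0.0729017 0.0627708 0.100551 1.49494
0.535874 1.46523 0.270026 0.0256332 0.314304 0.0548412 1.13472 0.00725548 1.03134 5.11767  2.4005 0.506309 0.880824 0.033644 0.373181 0.296798
0.813269 0.12341 0.373038 0.159351 0.36683 0.770155 0.00921881 0.374251 0.418779 0.858444 0.947713  4.6071 0.349064 0.765621 3.40024 2.35109
 1.2649  2.6077 0.103569 0.138336 0.592759 13.6251 0.0200024 0.0166445 0.483037 0.282132 0.0211351 0.74133 1.24991 2.88934 0.758169 4.03333
0.213077 0.906968 0.353293 0.216612 0.0892761 4.09659 12.2496 0.295459 2.16582 0.596849 0.319965 0.958169 0.590046 0.00962747 0.216085 1.05322
0.87047 8.05223  8.9795 1.55484 1.24437  16.892 0.0623845 0.346967 0.264855 1.55485 0.0931838 0.247939 0.889434 0.763554 0.190619 0.525346
0.0875652 0.01972 0.0272404 0.506923 0.0250274 3.99964 0.526532 0.0212218 1.49299 0.807459 0.190444 5.89381 1.84105 0.000168459 0.185143 0.0173251
1.32028 0.0288609 0.728558 0.419471 0.177128 0.621935 0.0680899 0.670257 0.0246595 0.467158 0.137047 3.64863 0.143938 0.37549 0.425178 0.0936148
0.480328 0.0332641 0.0298252 0.269973 1.04208 0.0953839 0.371023 5.94879 0.669615 0.970275 0.0978545 0.31176 0.779397 0.458852 0.294137 0.714639
6.31381 0.294419 0.224684 4.22745 0.898591 3.73178  1.2075 3.47303 5.19938 0.0367064 0.0327929 0.191367 0.0361047 0.177277 0.00376171 0.0153019
0.268155 11.3019 0.401611 3.53802 3.10139 0.213792 0.169144 3.09096 21.0597 1.42945 0.925452 0.0503283 0.0671475 0.238424 2.17304 1.70028
0.102931 0.0090992 1.22775 0.372393 3.37399 0.25845 1.54274 0.770504 0.294709 2.81095 36.0395 0.0439403 1.29872 0.443735 0.140187 0.0087201
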