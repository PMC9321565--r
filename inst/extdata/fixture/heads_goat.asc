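ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
5.43433 0.602243 0.743845 4.16801 0.00593222 3.95361 1.07569 0.170385 2.87175 1.78876 1.19969 2.46151 0.0337885 4.62525 17.6986 2.13091
1.93318 7.49009 1.94055 1.40835 0.357957 0.937555 6.09187 0.170324 0.344221 0.168641 5.15651 2.46475 8.50111 125.434 14.8188 7.12223
0.736915 0.138435 5.53785 0.489188 23.7486 3.10718 0.602579 1.32961 0.721455 5.79397 6.69694 9.66127 0.740064  9.5426 6.35668 0.165356
1.45414 0.661941 5.44821 3.62173 0.52541 1.25887 5.68726 4.45168 15.6518 0.807901 4.04552 7.25835 16.7198 29.5787 5.25405 175.541
10.9834 2.60053 0.518162 2.05596 1.68037 1.22512 3.26379 8.01132 7.93639 36.6243 10.3719 2.82043 5.08073 0.470461 2.94043 31.2816
3.87342 3.29716  2.3358 0.12275 2.29041 0.864203 4.68673 0.266133 2.68073 55.6621 55.8296 75.8461 19.6276 1.34829 1.11313 2.71681
3.90072 2.70889 0.902547 2.39653 4.14503 11.0848 0.114102 1.42419 4.12715 4.12092 2.93715 149.678  3.2176 3.28756 115.198 71.5638
4.27453 22.9826 0.119865 1.73776 5.65066  50.419 0.531203 0.157699 4.62551 3.00268 0.848067 2.04924 0.255729 13.2858 14.4971 5.77099
2.31489 14.5404 16.8242 0.792252 0.146484  91.107 100.254 5.36147 4.20968 47.4662 5.16671 70.0482 2.64745 0.452382  2.8904 8.67951
1.09034 43.8376 17.1968 20.1558 2.07956 70.1741 3.48867 0.615246 3.29268 6.03618 2.81831 0.632573 16.3481 29.2108 3.85997 3.52279
0.0853496 0.292331 0.225198 18.7374 0.688169 35.6576 8.81117 0.505297 13.1439 12.9355 5.11453 83.4897   38.57 0.00902025 0.741544 0.420331
1.38004 1.70454 6.10572 4.29341 2.04837 3.78134 1.37162  8.9736 0.401995 3.60031 0.61837 60.9497 0.821787 5.49088 0.67231 1.11538
 11.743 0.262493 1.91738 5.31358 15.6038  4.3208 3.72186 79.6985 6.45575 3.31958 12.9817 5.39524 6.99619  5.2109 1.33252 2.58614
41.8739 4.51376 2.03072 23.5871 21.9194 39.0585 22.1215 21.1757 39.4464 0.258085 0.161183 1.54708 2.63619 1.61518 0.124613 0.997352
2.97276 45.3403 10.3624 32.9978 8.07272 1.87149  2.5363 7.35944 93.5026 2.87534 3.87007  4.5802 0.142025 1.16403 2.18402 0.413037
1.08281 0.471448 15.8274 0.736209 2.06455 0.497031 27.7064 6.98224 2.35039 25.9264 132.945 0.109359 5.92653 3.78258 0.499307 0.640443
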