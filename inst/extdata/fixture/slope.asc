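ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
31.3687    33.7 31.4515  32.868 26.3319 8.73813 12.8383 4.76208 6.95241       0 7.03609 17.3852   19.86 11.6681 10.0739 6.34862
12.8785 18.5926 21.0788 22.3646 17.5731 5.39056 10.2785 7.07616 5.73364 2.68311 7.59453 19.7533  19.724 12.0048 6.13016 9.54214
8.64584 19.6863 21.8679 24.0051 15.8986 1.12813 4.79342 2.47237 1.50315 2.95612 3.45328 14.8378 11.4981 11.1277 4.96437 7.13761
3.83437 8.69236 9.52014 10.5247 5.49877       0       0       0       0 6.98234  3.3772 12.7327 14.1147 16.5481 4.65151 6.06604
13.2914 17.2333 16.8184 21.0575 11.7164       0       0 3.37639 0.146785 6.89998       0 0.555853 6.39523 13.5796 2.63979 4.73145
13.8332 17.3775 13.3458 17.4815 6.89362       0       0 1.92125       0 4.44072       0 0.199499 6.06496 19.4472 12.6597 14.1131
21.2059 18.9882 11.4142  13.403       0       0       0       0       0       0       0       0       0 8.35954       0 3.91079
26.6737  26.133 17.9965 23.1667 7.45681 5.03608 2.91111 2.95509       0 4.46555       0       0 1.99272 12.7284 4.65309 3.97049
27.4946 22.9933 12.0325 15.4801 3.21991 0.99894 1.93407       0 0.377498 5.06071       0       0       0 9.42302 7.17709 7.56871
28.1938 20.9088 6.43566 10.1074       0       0       0       0       0 4.45379 1.44962       0 7.38089 16.8304 11.9776 9.46925
 27.317 25.5994  13.916 18.8286 2.07597       0 3.50743 1.97087 3.44492 0.408543  3.1148 0.607314 1.63047 5.97765 1.71667       0
26.2613 27.8508  17.788 16.5267  5.2765 0.482505  7.2955 6.85028 5.06037       0 4.89667 1.87894 0.21972       0       0 0.0962399
30.7095 31.6796  23.731 23.9752 15.3601 9.58685 11.5724 8.21166 3.93206       0       0       0       0       0       0       0
19.7789 25.5009 22.2075 20.6852 15.9735 9.91357  9.6688 18.0533 13.3871 9.64976 15.0875 12.7401 11.3264 7.19522       0 1.16978
7.57479 15.3402 17.3118 12.9434 11.0603 2.27085 1.51462 12.1022 4.91047       0 1.96931 1.45832       0       0       0       0
18.4055 23.2117 26.3465 29.4668 23.5225 12.5629 3.33769 17.8104  6.0491 2.22214 0.73897 9.11773 5.95098 4.09892       0 0.687773
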