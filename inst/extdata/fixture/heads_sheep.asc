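ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
0.925631 1.29209 0.648589  7.5415 0.0876086  2.4989 0.0820817 0.331458 2.19533 1.24359 1.40576 4.29526 2.52496  11.842 9.78067 1.71758
0.167472 5.74344 1.79186 2.28324 0.68683 0.922757 0.638719 0.278787 0.358978 0.14449 1.14801 0.625777 5.96171 23.0118 17.0286 19.2708
2.63722 0.296157 2.42454 1.22792 2.43453 3.49575 0.399909 6.45916 0.892458 3.57486  37.806 10.2475 2.06332 7.89144 10.0548 0.380863
0.476038 1.79833 6.93199 2.66643 0.154786 3.64251 0.993596 7.27544 24.4464 0.0966082 3.10016 26.5605 15.2557 5.47595 5.19647 120.068
1.69965 0.42472 0.790235 6.29925 1.38704 2.28073 3.21223 1.95965 0.768305 21.0962 9.89414 5.57206 0.487509 0.102639 0.622272  8.4194
4.53026 11.5957 1.80002 0.0953114 12.4733 0.941805  11.331 0.339769 8.48405 25.7974 109.326 44.5938 9.57393 2.92905 0.883359 3.82834
15.6294  2.1228 0.22022 2.59116  1.6619 6.09065 0.119779 0.808732 1.93309 1.11111 9.34797 52.8459 4.17855 2.45336 25.9881 64.7382
4.99421 31.3897 0.228952 0.433025  14.951 42.0244 0.181691 0.159207 6.25647 0.933521 0.886326 3.52133 2.02316 9.82059 9.51248 27.7397
1.94329 33.6115 14.5776 5.01178 0.635588 68.9966  212.36 1.42996 11.4716 20.5375 16.5858 5.55131 3.82921 0.177007 2.02304 4.67986
1.77212 51.3627 16.4505 12.3596 11.7355 35.8347 1.95835 6.42046 1.80987 18.1057  5.4514 0.713769 7.45737 3.56171 3.24511 5.72648
0.525141 0.368244 0.420835 11.1374 4.00125 30.6902 3.90216 0.763311 36.1947 7.55732 0.726036 154.712 8.23218 0.00246965 3.98127 0.174058
11.5782 1.34468 11.1232 0.482178 1.35805 6.28438 1.95773 4.04032 0.59198 0.819444 1.40615 24.7746 0.438458 3.36937 1.84205 2.02093
15.1413 0.60188 2.09957 5.24259  15.547 1.65822 16.6752 80.2495 4.00637 4.75565  11.076 6.08447 8.77356 16.9932 7.94811 9.08428
55.2595 2.70362 2.37896 37.1566 12.6415 21.5058 8.16291  3.8697 134.898 0.757014 0.160211 0.65032 1.77556 0.615986 0.0417808 0.995265
1.04179 2.02251 11.1984 15.4144 39.4994 3.79814 1.94331 4.02171 60.6443 11.2428 3.24802 1.64519 0.379491 0.174767 14.0816 35.2612
2.16573 0.509247 5.60575 1.24657 22.1034 1.32708 18.6908 1.97893 2.61968  108.42 131.739 0.155341 20.7531 6.25427 0.93746 0.0113657
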