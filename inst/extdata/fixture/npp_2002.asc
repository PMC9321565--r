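ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
291.707 290.479 190.672 222.257 277.915 293.783 276.868 203.725 261.453 259.612 295.461 366.031 260.691 393.421 282.105 328.046
295.663 241.902 211.887 216.173  293.05 336.858 240.147 204.565 142.282 242.057 240.037 327.898 311.405 300.202 282.418 315.097
338.671 336.285 282.888 369.729 368.376 322.436 297.444 253.727 230.204 287.601 321.504 363.522 354.442 447.466 326.531 405.567
258.966 290.455  210.35 255.203 449.775 327.699 261.858 188.334  179.67 332.776  311.48 240.078 306.729 313.362 327.848 416.586
299.966  235.02  210.51 233.574 341.291 373.122 248.673 239.047 176.022 270.269 308.088 249.916 168.007 271.306 280.905  328.97
292.415 209.739 214.473 229.496 228.389 266.742 208.638 189.977 172.115 229.054 272.953   189.1     174 196.283  192.54 240.784
355.604  236.99  259.13 314.955 264.452 265.047 212.943 162.185  196.14 196.393 196.404 216.454 146.745 219.041  197.53 208.283
221.618 245.012 272.973 226.863 214.931 274.551 233.156 205.065 269.456 254.578 266.703 186.068 186.415 179.537 165.605 148.522
265.049 234.472 240.324 272.022 272.433 205.889 195.573 217.018 223.521 288.217 239.794 231.438 201.207  200.81 206.732 188.931
186.398 172.015 191.761 218.528 179.226 199.396 200.202 153.029 199.865  199.63  195.08 188.944 175.815 152.964 179.718 152.924
170.607 142.882 177.534 241.738 147.335 180.281 218.519 170.716 236.289 228.505 177.028 232.795  187.26 145.482 146.812 112.534
173.098 162.479 207.276 189.075 168.564 183.156  214.86 137.941   186.3 199.589 188.006 262.075 201.776 130.024 201.843  178.77
157.521 154.994 200.632  221.17 186.862 215.731 327.697 287.134 272.972 356.088 267.108 332.945 289.665 211.072  257.42 169.983
165.401 168.556 191.584 166.118 172.013 180.744 228.373 212.544  227.16 314.285 414.431 584.677 393.659 386.917 471.927 259.742
197.312 170.391 194.573 155.952 192.449 174.967 209.832 219.631 273.292  358.48 426.334 609.904 520.946 439.644 477.768 256.163
139.838 157.309 183.336 160.972 226.131 182.853 308.738 297.615   346.7 377.591 490.638 663.131 556.212 410.787 438.048  270.38
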