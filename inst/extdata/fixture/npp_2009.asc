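ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
245.808 263.428 233.683 200.172 258.269 292.126 281.761 248.678 213.866 225.389 362.294 351.362  265.16 362.508 265.873 325.116
329.488 321.809 208.376 223.195 197.182 280.189 219.083 192.887 200.502 217.544 275.358  278.95 226.892 322.965 293.796 291.072
326.735 267.138 236.088 320.871 302.598 342.517 264.102 225.892 202.261 309.442 336.712 390.353 330.968 426.598  358.28 424.482
286.188 230.759 239.992 212.634   350.7 306.577  227.44 202.448 177.191 272.147 342.666 302.349 221.194 297.845 315.275 373.923
295.897 243.361 179.647 200.082 284.044  308.92 234.833 195.909 250.061 268.811 268.659 229.211 202.454 257.924 304.319 303.661
 365.99 243.091 209.766 239.765 224.443 232.181 207.168 153.714 207.568 210.164 232.506 199.577 143.069 210.594 176.305 197.138
362.446 325.846 241.552 320.988 312.275 309.871 189.946 193.776 162.153 208.402 214.584 156.204 154.735 161.277 164.557 192.552
310.443 221.078 273.153 205.617  256.39 273.586 205.511 188.405 212.122 268.036 219.017 210.965 159.514  122.43 182.902 145.968
258.981 237.423 195.935 280.024 216.831 227.574 201.151 190.785 275.548 273.311 189.192 200.933 173.188 173.667 188.158  179.98
237.106 203.118 206.177 200.799 209.144 204.757 219.675 170.971 213.015 210.713 158.854 199.994 138.102 128.222 158.065 131.764
171.827 156.914 181.636 215.207 170.085 223.482  218.61 187.033 196.693 223.481 198.359  254.98 206.979 165.581 153.781 123.455
160.022 209.654 186.023 240.196 161.766 180.588  230.59 151.389 238.588 278.062 187.219 234.978 196.593 144.338  210.93 129.175
148.391 187.148  219.38 217.844   244.2 226.233 313.652  308.97 271.827 375.211  277.33 400.566 361.345 222.256 301.064 152.137
141.155 177.881 176.167 170.147 141.043 142.846 247.402  289.74  373.04 352.474 348.638 612.431 437.958 371.297 468.907 232.698
180.848 175.214 174.062 191.967 165.673 167.362 255.707 236.718 360.934 393.039 515.403 704.294 588.799 549.686 491.383 270.296
193.308 188.269 197.262 191.292 260.756 185.304 296.265 276.744 402.607 463.641 558.313 722.228 550.589 620.596 562.228 308.446
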