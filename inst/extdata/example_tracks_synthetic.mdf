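MTrackJ 1.5.1 Data File
Displaying true true true
Cluster 1 FF0000
Track 1 FF0000 true
Point 1 20.370 23.044 1.0 1 1
Point 2 20.513 22.904 1.0 2 1
Point 3 20.655 22.764 1.0 3 1
Point 4 20.798 22.624 1.0 4 1
Point 5 20.941 22.484 1.0 5 1
Track 2 FF0000 true
Point 1 22.702 24.979 1.0 1 1
Point 2 23.899 26.044 1.0 2 1
Point 3 25.104 26.967 1.0 3 1
Point 4 23.673 25.405 1.0 4 1
Point 5 22.338 23.601 1.0 5 1
Cluster 2 FF0000
Track 1 FF0000 true
Point 1 3.048 73.481 1.0 3 1
Point 2 3.246 73.508 1.0 4 1
Point 3 3.444 73.536 1.0 5 1
Point 4 3.642 73.564 1.0 6 1
Point 5 3.841 73.591 1.0 7 1
Track 2 FF0000 true
Point 1 1.302 70.914 1.0 3 1
Point 2 1.434 71.056 1.0 4 1
Point 3 1.690 71.148 1.0 5 1
Point 4 1.788 70.956 1.0 6 1
Point 5 2.035 71.139 1.0 7 1
Cluster 3 FF0000
Track 1 FF0000 true
Point 1 42.896 55.936 1.0 8 1
Point 2 42.823 56.123 1.0 9 1
Point 3 42.751 56.309 1.0 10 1
Point 4 42.679 56.496 1.0 11 1
Point 5 42.606 56.682 1.0 12 1
Point 6 42.534 56.869 1.0 13 1
Track 2 FF0000 true
Point 1 42.436 57.996 1.0 8 1
Point 2 41.868 60.282 1.0 9 1
Point 3 41.730 60.587 1.0 10 1
Point 4 41.651 60.519 1.0 11 1
Point 5 41.659 60.812 1.0 12 1
Point 6 41.973 58.955 1.0 13 1
Cluster 4 FF0000
Track 1 FF0000 true
Point 1 26.809 19.902 1.0 13 1
Point 2 26.713 19.727 1.0 14 1
Point 3 26.618 19.551 1.0 15 1
Point 4 26.522 19.376 1.0 16 1
Track 2 FF0000 true
Point 1 27.191 22.037 1.0 13 1
Point 2 27.540 23.840 1.0 14 1
Point 3 27.625 25.987 1.0 15 1
Point 4 27.154 22.464 1.0 16 1
Cluster 165 FF0000
Track 1 FF0000 true
Point 1 40.100 70.000 1.0 1 1
Point 2 40.200 70.000 1.0 2 1
Point 3 40.300 70.000 1.0 3 1
Point 4 40.400 70.000 1.0 4 1
Point 5 40.500 70.000 1.0 5 1
Point 6 40.600 70.000 1.0 6 1
Point 7 40.700 70.000 1.0 7 1
Point 8 40.800 70.000 1.0 8 1
Point 9 40.900 70.000 1.0 9 1
Point 10 41.000 70.000 1.0 10 1
Point 11 41.100 70.000 1.0 11 1
Point 12 41.200 70.000 1.0 12 1
Point 13 41.300 70.000 1.0 13 1
Point 14 41.400 70.000 1.0 14 1
Point 15 41.500 70.000 1.0 15 1
Point 16 41.600 70.000 1.0 16 1
Track 2 FF0000 true
Point 1 41.100 71.000 1.0 1 1
Point 2 41.200 71.000 1.0 2 1
Point 3 41.300 71.000 1.0 3 1
Point 4 41.400 71.000 1.0 4 1
Point 5 41.500 71.000 1.0 5 1
Point 6 41.600 71.000 1.0 6 1
Point 7 41.700 71.000 1.0 7 1
Point 8 41.800 71.000 1.0 8 1
Point 9 41.900 71.000 1.0 9 1
Point 10 42.000 71.000 1.0 10 1
Point 11 42.100 71.000 1.0 11 1
Point 12 42.200 71.000 1.0 12 1
Point 13 42.300 71.000 1.0 13 1
Point 14 42.400 71.000 1.0 14 1
Point 15 42.500 71.000 1.0 15 1
Point 16 42.600 71.000 1.0 16 1
End of MTrackJ Data File
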